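# Mixed-model equations against closed forms and a dense GLS oracle;
# EM/AI-REML against analysis-of-variance and boundary cases.

library(Matrix)

reml_data <- function(seed, n_target = 250, va = NULL, ...) {
  args <- list(seed = seed, career_length_distribution = c(0, 0, 0, 1), ...)
  if (!is.null(va)) args$var_additive <- va
  cfg <- do.call(tiny_config, args)
  cfg$n_recorded_mares_target <- as.integer(n_target)
  sim <- simulate_pedigree(cfg)
  ev <- simulate_careers(sim)
  fu <- apply_editing(ev, sim$pedigree, editing_rules(min_seasons = 6))
  kin <- kinship(sim$pedigree)
  fu$lfr <- fu$f6 / 6
  fu$f_coef <- kin$f[as.character(fu$mare_id)]
  fu$af_class <- factor(fu$af_class)
  list(data = fu, kin = kin, sim = sim)
}

test_that("a single phenotyped founder solves the 2x2 closed form", {
  y <- 0.8
  mme <- build_mme(y, NULL, Z = list(additive = matrix(1, 1, 1)),
                   Ginv = list(additive = matrix(1, 1, 1)),
                   lambda = c(additive = 1))
  sol <- solve_mme(mme)
  expect_equal(sol$additive, y / 2)         # (1 + lambda) a = y
})

test_that("infinite variance ratios recover ordinary least squares", {
  set.seed(4)
  n <- 40
  X <- cbind(1, rnorm(n))
  g <- sample(1:5, n, TRUE)
  Z <- sparseMatrix(i = seq_len(n), j = g, x = 1, dims = c(n, 5))
  y <- drop(X %*% c(2, -1)) + rnorm(n)
  mme <- build_mme(y, X, Z = list(herd = Z),
                   Ginv = list(herd = Diagonal(5)),
                   lambda = c(herd = 1e12))
  sol <- solve_mme(mme)
  expect_equal(sol$fixed, unname(coef(lm(y ~ X - 1))), tolerance = 1e-6)
  expect_lt(max(abs(sol$herd)), 1e-9)
})

test_that("MME solutions equal dense GLS + BLUP on a toy dataset", {
  set.seed(11)
  ped <- random_pedigree(10, 25, 3, seed = 21)
  rec <- sample(ped$animal[ped$sire != 0], 50, replace = FALSE)
  A <- build_A(ped)
  D <- build_D(ped, A)
  vc <- c(herd = 0.3, additive = 1.2, dominance = 0.5, residual = 2)
  n <- length(rec)
  midx <- match(rec, ped$animal)
  gf <- factor(sample(1:6, n, TRUE))
  X <- cbind(1, rnorm(n))
  Zh <- model.matrix(~ gf - 1)
  y <- rnorm(n, sd = 2)
  # dense oracle on the marginal covariance
  V <- vc["herd"] * tcrossprod(Zh) + vc["additive"] * A[midx, midx] +
    vc["dominance"] * D[midx, midx] + vc["residual"] * diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u_a <- drop(vc["additive"] * A[, midx] %*% Vi %*% r)
  u_d <- drop(vc["dominance"] * D[, midx] %*% Vi %*% r)
  u_h <- drop(vc["herd"] * t(Zh) %*% Vi %*% r)
  # Henderson route
  dat <- data.frame(mare_id = rec, y = y, x = X[, 2], eu_by = gf)
  sol <- solve_blup(dat, y ~ x, ped, vc, id = "mare_id", group = "eu_by")
  expect_equal(unname(sol$fixed), drop(beta), tolerance = 1e-7)
  expect_equal(unname(sol$additive), unname(u_a), tolerance = 1e-7)
  expect_equal(unname(sol$dominance), unname(u_d), tolerance = 1e-7)
  expect_equal(unname(sol$herd), unname(u_h), tolerance = 1e-7)
})

test_that("REML equals ANOVA components on balanced founders-only data", {
  set.seed(7)
  ngrp <- 25; k <- 6
  n <- ngrp * k
  sig_h <- 0.4; sig_e <- 1.1
  grp <- rep(seq_len(ngrp), each = k)
  y <- rnorm(ngrp, 0, sqrt(sig_h))[grp] + rnorm(n, 0, sqrt(sig_e))
  dat <- data.frame(mare_id = seq_len(n), value = y,
                    eu_by = sprintf("g%02d", grp))
  ped <- data.frame(animal = seq_len(n), sire = 0L, dam = 0L)
  fit <- lfr_reml(value ~ 1, dat, ped, random = "herd")
  av <- anova(aov(y ~ factor(grp)))
  msb <- av[["Mean Sq"]][1]; msw <- av[["Mean Sq"]][2]
  expect_equal(unname(fit$varcomp["residual"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["herd"]), (msb - msw) / k,
               tolerance = 1e-5)
})

test_that("restricted logL never decreases across iterations", {
  rd <- reml_data(31)
  fit <- lfr_reml(lfr ~ af_class + f_coef, rd$data, rd$kin)
  expect_true(all(diff(fit$logl_path) > -1e-8))
  expect_true(fit$converged)
  # V-form BLUP coincides with the Henderson MME route at the same variances
  sol <- solve_blup(transform(rd$data, value = lfr), value ~ af_class + f_coef,
                    rd$kin, fit$varcomp)
  expect_equal(unname(sol$additive), unname(fit$ebv), tolerance = 1e-6)
})

test_that("a trait simulated without additive variance estimates h2 near 0", {
  h2s <- sapply(c(41, 42, 43, 44, 45), function(s) {
    rd <- reml_data(s, n_target = 220, va = 0)
    fit <- lfr_reml(lfr ~ af_class, rd$data, rd$kin)
    fit$h2
  })
  expect_lt(mean(h2s), 0.08)
  expect_true(all(h2s < 0.25))
})

test_that("EBV accuracy grows with the simulated additive variance", {
  cor_truth <- function(seed, va) {
    rd <- reml_data(seed, n_target = 260, va = va)
    fit <- lfr_reml(lfr ~ af_class, rd$data, rd$kin)
    truth <- rd$sim$truth
    rec <- truth$animal %in% rd$data$mare_id
    if (va == 0) return(NA_real_)
    cor(fit$ebv[as.character(truth$animal[rec])], truth$bv[rec])
  }
  lo <- sapply(51:54, cor_truth, va = 2e-3)
  hi <- sapply(51:54, cor_truth, va = 12e-3)
  expect_gt(mean(hi), mean(lo))
  expect_gt(mean(hi), 0.3)
})

test_that("identical phenotypes give zero breeding values", {
  rd <- reml_data(61, n_target = 150)
  dat <- rd$data
  dat$lfr <- 0.7
  fit <- suppressWarnings(lfr_reml(lfr ~ 1, dat, rd$kin))
  expect_lt(max(abs(fit$ebv)), 1e-6)
})

test_that("heritability and its delta-method standard error are exact", {
  vc <- c(herd = 0.141, additive = 4.848, dominance = 1.628,
          residual = 13.426)
  expect_lt(abs(heritability(vc) - 0.242), 5e-4)
  expect_equal(heritability(c(additive = 0, residual = 1)), 0)
  # degenerate sampling covariances give SE 0
  z4 <- matrix(0, 4, 4, dimnames = list(names(vc), names(vc)))
  expect_equal(se_heritability(vc["additive"], sum(vc), z4), 0)
  expect_equal(se_heritability(0, 1, z4), 0)
  # hand-checked 2x2 case: h2 = 0.25, Var(a)=0.04, Var(p)=0.16, Cov=0.02
  se <- se_heritability(1, 4, matrix(c(0.04, 0.02, 0.02, 0.16), 2))
  expect_equal(se, 0.25 * sqrt(0.04 / 1 + 0.16 / 16 - 2 * 0.02 / 4),
               tolerance = 1e-12)
})

test_that("fit object methods expose the expected quantities", {
  rd <- reml_data(71, n_target = 150)
  fit <- lfr_reml(lfr ~ af_class, rd$data, rd$kin)
  expect_s3_class(fit, "lfr_reml")
  expect_named(coef(fit), c("(Intercept)", "af_class4"))
  expect_length(residuals(fit), nrow(rd$data))
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-10)
  expect_equal(AIC(fit), -2 * fit$logLik + 8)
  expect_equal(unname(predict(fit, rd$data$mare_id[1:3])),
               unname(fit$ebv[as.character(rd$data$mare_id[1:3])]))
  sm <- summary(fit)
  expect_equal(sm$varcomp$estimate, unname(fit$varcomp))
  expect_output(print(fit), "Variance components")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(rd$data), 3L))
  expect_equal(sd(sims$sim_1) / sqrt(fit$var_phenotypic), 1,
               tolerance = 0.35)
})
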