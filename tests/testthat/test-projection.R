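# Sixth-season projection, LFR construction and validation statistics.

training_fixture <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) {
      sim <- simulate_pedigree(small_config(
        seed = 6, career_length_distribution = c(0, 0, 0, 1)))
      ev <- simulate_careers(sim)
      tr <<- apply_editing(ev, sim$pedigree, editing_rules(min_seasons = 6))
    }
    tr
  }
})

test_that("equations fit recovers an exact linear training relation", {
  tr <- training_fixture()
  tr2 <- tr
  tr2$f6 <- tr2$f3 + 2L                      # deterministic relation
  fit <- fit_projection(tr2, "equations", 3)
  cf <- coef(fit$eq_fit)
  expect_equal(unname(cf["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(cf["fk"]), 1, tolerance = 1e-8)
  expect_equal(unname(cf["af4"]), 0, tolerance = 1e-8)
  sub <- tr2[tr2$n_seasons == 6, ]
  sub$n_seasons <- 3L
  expect_equal(project_foals(sub, fit), pmin(sub$f3 + 2, 6))
})

test_that("a single AF class degrades gracefully", {
  tr <- training_fixture()
  tr3 <- tr[tr$af_class == 3L, ]
  fit <- fit_projection(tr3, "equations", 4)
  expect_false(fit$two_af)
  expect_true(all(is.finite(coef(fit$eq_fit))))
  fitc <- fit_projection(tr3, "coefficients", 4)
  expect_length(fitc$factors, 1L)
})

test_that("mean equations prediction equals mean actual (normal equations)", {
  tr <- training_fixture()
  fit <- fit_projection(tr, "equations", 4)
  expect_equal(mean(fitted(fit$eq_fit)), mean(tr$f6), tolerance = 1e-10)
})

test_that("projections are clamped to the feasible foal range", {
  tr <- training_fixture()
  for (m in c("coefficients", "equations")) {
    fit <- fit_projection(tr, m, 3)
    sub <- tr
    sub$n_seasons <- 3L
    p <- project_foals(sub, fit)
    expect_true(all(p >= sub$f3 & p <= 6))
  }
  fit <- fit_projection(tr, "equations", 3)
  expect_error(project_foals(tr, fit), "mismatch")
})

test_that("LFR and arcsine transforms follow their closed forms", {
  expect_equal(compute_lfr(6), 1)
  expect_equal(compute_lfr(0), 0)
  expect_equal(compute_lfr(c(3, 4.5)), c(0.5, 0.75))
  expect_error(compute_lfr(7), "0, 6")
  expect_equal(arcsine_lfr(0.5), asin(0.5))
  expect_equal(round(arcsine_lfr(0.5), 4), 0.5236)
  expect_equal(arcsine_lfr(1), pi / 2)
  expect_equal(arcsine_lfr(0.5, variant = "sqrt"), asin(sqrt(0.5)))
  expect_error(arcsine_lfr(1.2), "0, 1")
  # delta-method moment check that motivates the asin(p) reading:
  # sd 0.142 at mean 0.700 propagates to ~0.199 on the arcsine scale
  expect_equal(0.142 / sqrt(1 - 0.7^2), 0.199, tolerance = 0.005)
  # monotone: ranks identical between linear and arcsine expressions
  x <- runif(50)
  expect_equal(rank(arcsine_lfr(x)), rank(x))
})

test_that("PSB, MAD and SDR match hand arithmetic and their invariants", {
  v <- validation_stats(c(1, 2), c(1, 1))
  expect_equal(v$psb, 20)                   # 100 * 1 / 5
  expect_equal(v$mad, 0.5)
  expect_equal(v$sdr, sqrt(0.5), tolerance = 1e-10)

  y <- c(2, 3, 5, 4)
  perf <- validation_stats(y, y)
  expect_equal(c(perf$psb, perf$mad, perf$sdr), c(0, 0, 0))
  # zero iff predictions equal actuals
  off <- validation_stats(y, y + 0.1)
  expect_true(off$psb > 0 && off$mad > 0)
  # PSB is invariant under common rescaling
  a <- c(1, 3, 4); p <- c(2, 2, 5)
  expect_equal(validation_stats(a, p)$psb,
               validation_stats(10 * a, 10 * p)$psb)
  expect_error(validation_stats(c(0, 0), c(1, 1)), "zero")
  expect_error(validation_stats(numeric(0), numeric(0)), "non-empty")
})

test_that("leave-one-out validation improves with the projection horizon", {
  tr <- training_fixture()
  for (m in c("coefficients", "equations")) {
    psb <- sapply(3:5, function(k) validate_projection(tr, m, k)$psb)
    expect_true(all(diff(psb) < 0))
  }
})

test_that("phenotype assembly routes actual and projected careers", {
  sim <- simulate_pedigree(small_config(seed = 13))
  ev <- simulate_careers(sim)
  training <- apply_editing(ev, sim$pedigree, editing_rules(min_seasons = 6))
  full <- apply_editing(ev, sim$pedigree, editing_rules(min_seasons = 3))
  fits_c <- setNames(lapply(3:5, function(k)
    fit_projection(training, "coefficients", k)), 3:5)
  fits_e <- setNames(lapply(3:5, function(k)
    fit_projection(training, "equations", k)), 3:5)
  f <- compute_inbreeding(sim$pedigree)
  names(f) <- sim$pedigree$animal
  ph <- assemble_phenotypes(full, fits_c, fits_e, inbreeding = f)
  expect_equal(nrow(ph), 4L * nrow(full))
  expect_setequal(unique(ph$trait),
                  c("lfr_c", "lfr_e", "arcsine_c", "arcsine_e"))
  complete <- full$mare_id[full$n_seasons >= 6L]
  pc <- ph[ph$trait == "lfr_c", ]
  expect_true(all(pc$source[pc$mare_id %in% complete] == "actual"))
  expect_true(all(pc$source[!pc$mare_id %in% complete] == "projected"))
  # complete careers contribute identical values to both linear traits
  pe <- ph[ph$trait == "lfr_e", ]
  iC <- match(complete, pc$mare_id); iE <- match(complete, pe$mare_id)
  expect_equal(pc$value[iC], pe$value[iE])
  expect_true(all(ph$value[ph$trait %in% c("lfr_c", "lfr_e")] >= 0 &
                    ph$value[ph$trait %in% c("lfr_c", "lfr_e")] <= 1))
  ar <- ph$value[ph$trait %in% c("arcsine_c", "arcsine_e")]
  expect_true(all(ar >= 0 & ar <= pi / 2 + 1e-12))
  # duplicated mare triggers the guard
  expect_error(assemble_phenotypes(rbind(full, full[1, ]), fits_c, fits_e),
               "more than once")
})

test_that("moment helpers agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(1)
  x <- rnorm(500)^2
  expect_equal(skewness(x), e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(kurtosis(x), e1071::kurtosis(x, type = 1), tolerance = 1e-12)
})
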