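# Synthetic studbook generator: determinism, pedigree validity, liability
# model behavior and truncation semantics.

test_that("minimal configuration yields founders plus offspring only", {
  cfg <- sim_config(n_founders = 2L, n_generations = 1L,
                    n_recorded_mares_target = 5L,
                    sires_per_generation = 1L, seed = 3)
  sim <- simulate_pedigree(cfg)
  expect_equal(sum(sim$pedigree$generation == 0L), 2L)
  kids <- sim$pedigree[sim$pedigree$generation > 0L, ]
  expect_true(all(kids$sire %in% sim$pedigree$animal))
  expect_true(all(kids$dam %in% sim$pedigree$animal))
})

test_that("identical config and seed reproduce tables exactly", {
  cfg <- tiny_config(seed = 21)
  s1 <- simulate_pedigree(cfg)
  s2 <- simulate_pedigree(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$truth, s2$truth)
  e1 <- simulate_careers(s1)
  e2 <- simulate_careers(s2)
  expect_identical(e1, e2)
})

test_that("pedigree is acyclic with parents born earlier and sexes consistent", {
  sim <- simulate_pedigree(small_config(seed = 8))
  ped <- sim$pedigree
  expect_silent(compute_inbreeding(ped))      # would error on a cycle
  pos <- match(ped$sire, ped$animal)
  known <- !is.na(pos)
  expect_true(all(ped$birth_year[pos[known]] < ped$birth_year[known]))
  expect_true(all(ped$sex[pos[known]] == "M"))
  dpos <- match(ped$dam, ped$animal)
  dknown <- !is.na(dpos)
  expect_true(all(ped$sex[dpos[dknown]] == "F"))
})

test_that("degenerate liability gives a foal every season", {
  cfg <- tiny_config(seed = 4, var_herd = 0, var_additive = 0,
                     var_dominance = 0, var_residual = 0,
                     mean_lfr_liability = 1.0,
                     inbreeding_depression_slope = 0, af4_effect = 0)
  sim <- simulate_pedigree(cfg)
  ev <- simulate_careers(sim)
  expect_true(all(ev$event_type == "F"))
  tc <- attr(ev, "truth_careers")
  expect_true(all(tc$foals6_true == 6L))
})

test_that("with all variances zero the realized LFR converges to the mean", {
  cfg <- sim_config(n_founders = 200L, n_generations = 6L,
                    n_recorded_mares_target = 1500L,
                    sires_per_generation = 25L,
                    var_herd = 0, var_additive = 0, var_dominance = 0,
                    var_residual = 0, inbreeding_depression_slope = 0,
                    af4_effect = 0, mean_lfr_liability = 0.7,
                    career_length_distribution = c(0, 0, 0, 1), seed = 12)
  sim <- simulate_pedigree(cfg)
  ev <- simulate_careers(sim)
  tc <- attr(ev, "truth_careers")
  lfr <- tc$foals6_true / 6
  n <- nrow(tc)
  # analytic oracle: stochastic rounding of 6*0.7 = 4.2 has mean 4.2 and
  # variance 0.2*0.8 on the count scale
  expect_equal(mean(lfr), 0.7, tolerance = 3 * sqrt(0.16 / 36 / n) / 0.7)
  expect_true(all(tc$foals6_true %in% 4:5))
})

test_that("careers respect lengths, ages and realized-count bounds", {
  sim <- simulate_pedigree(small_config(seed = 15))
  ev <- simulate_careers(sim)
  tc <- attr(ev, "truth_careers")
  counts <- table(ev$mare_id)
  expect_true(all(tc$n_seasons %in% 3:6))
  expect_equal(unname(counts[as.character(tc$mare_id)]),
               tc$n_seasons, ignore_attr = TRUE)
  first <- ev[ev$season == 1L, ]
  expect_true(all(first$age_months >= 36L & first$age_months <= 59L))
  foals_obs <- tapply(ev$event_type == "F", ev$mare_id, sum)
  expect_true(all(foals_obs <= tc$n_seasons[match(names(foals_obs),
                                                  as.character(tc$mare_id))]))
  expect_true(all(tc$foals6_true >= 0 & tc$foals6_true <= 6))
})

test_that("career-length mass on 3-5 seasons leaves every mare censored", {
  cfg <- tiny_config(seed = 5, career_length_distribution =
                       c(`3` = 0.4, `4` = 0.3, `5` = 0.3, `6` = 0))
  ev <- simulate_careers(simulate_pedigree(cfg))
  expect_lt(max(table(ev$mare_id)), 6L)
})

test_that("founder breeding values match the additive variance", {
  cfg <- sim_config(n_founders = 1500L, n_generations = 1L,
                    n_recorded_mares_target = 10L,
                    sires_per_generation = 5L, seed = 30)
  sim <- simulate_pedigree(cfg)
  bvf <- sim$truth$bv[sim$pedigree$generation == 0L]
  rel_tol <- 3 * sqrt(2 / length(bvf))        # SE of a sample variance
  expect_equal(var(bvf), cfg$var_additive,
               tolerance = rel_tol * cfg$var_additive / var(bvf))
})

test_that("offspring breeding values regress on the mid-parent with slope 1", {
  sim <- simulate_pedigree(small_config(seed = 44))
  ped <- sim$pedigree
  tr <- sim$truth
  kids <- ped$sire != 0L & ped$dam != 0L
  mp <- 0.5 * (tr$bv[match(ped$sire[kids], ped$animal)] +
                 tr$bv[match(ped$dam[kids], ped$animal)])
  slope <- coef(lm(tr$bv[kids] ~ mp))[2]
  expect_equal(unname(slope), 1, tolerance = 0.12)
})

test_that("truncation keeps first k seasons and drops short careers", {
  sim <- simulate_pedigree(tiny_config(seed = 9))
  ev <- simulate_careers(sim)
  complete <- simulate_careers(simulate_pedigree(
    tiny_config(seed = 9, career_length_distribution = c(0, 0, 0, 1))))
  t3 <- truncate_careers(ev, 3)
  expect_true(all(table(t3$mare_id) == 3L))
  lens <- table(ev$mare_id)
  t5 <- truncate_careers(ev, 5)
  expect_false(any(names(lens)[lens < 5] %in% t5$mare_id))
  # idempotent composition on complete careers
  expect_equal(truncate_careers(truncate_careers(complete, 4), 3),
               truncate_careers(complete, 3), ignore_attr = TRUE)
  expect_error(truncate_careers(ev, 6), "3, 4, 5")
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(sim_config(n_founders = 1), "at least 2")
  expect_error(sim_config(var_additive = -1), "non-negative")
  expect_error(sim_config(career_length_distribution = c(1, 1, 1, 1)),
               "summing to 1")
  cfg <- tiny_config()
  expect_error(simulate_careers(data.frame(), NULL, cfg), "empty|required")
})
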