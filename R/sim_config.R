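#' Configuration for the synthetic studbook generator
#'
#' Collects every tunable of the synthetic pedigree and career generator in a
#' single validated list.  The defaults emulate a heavy-draught-horse studbook
#' population: about 3,000 recorded mares on a pedigree of roughly 6,800
#' animals over 12 discrete generations, careers of 3 to 6 annual breeding
#' seasons starting at age 3 or 4, and variance components on the lifetime
#' foaling rate (LFR) scale equal to the reference estimates for the Italian
#' Heavy Draught Horse population (herd 0.141e-3, additive 4.848e-3,
#' dominance 1.628e-3, residual 13.426e-3).
#'
#' @param n_founders Number of founder animals (unknown parents), split over
#'   two early birth cohorts. Must be at least 2.
#' @param n_generations Number of discrete offspring cohorts.
#' @param n_recorded_mares_target Approximate number of mares that receive
#'   reproductive careers.
#' @param sires_per_generation Number of stallions drawn as sires for each
#'   offspring cohort (hierarchical half-sib families).
#' @param eu_count Number of environmental units (area x rearing-system
#'   groups of stud farms).
#' @param birth_year_range Two-element integer vector; offspring cohorts are
#'   born every two years across this range, founders shortly before it.
#' @param p_first_foaling_age3 Probability that a mare's first foaling occurs
#'   in the 3-year-old age class (36-47 months) rather than at 4 (48-59).
#' @param var_herd,var_additive,var_dominance,var_residual Variance
#'   components on the realized LFR scale (proportion squared).
#' @param inbreeding_depression_slope Change in foaling probability per unit
#'   inbreeding coefficient (LFR units; negative = depression).
#' @param mean_lfr_liability Baseline per-season foaling probability for a
#'   non-inbred age-3 mare with average genetic and herd effects.
#' @param career_length_distribution Probabilities over 3, 4, 5, 6 registered
#'   breeding seasons (named or positional, must sum to 1).
#' @param af4_effect Fixed shift in foaling probability for mares first
#'   foaling at age 4 (LFR units).
#' @param abortion_share Fraction of non-foaling seasons labelled abortion
#'   ("A"); the remainder are open ("O").
#' @param residual_shape `"left-skewed"` (default): the mare-level residual
#'   is a reflected standardized gamma (shape 1.5, skewness about -1.6),
#'   reflecting a minority of subfertile careers below a concentrated
#'   healthy mode, as seen in the left-skewed distribution of the trait;
#'   `"gaussian"` draws a normal residual of the same variance.
#' @param season_model `"exchangeable"` (default): the six-season foal count
#'   is the stochastic rounding of `6 * pi` placed in random seasons, and the
#'   mare-level residual is drawn with variance `var_residual - 1/216` so the
#'   realized LFR variance decomposition matches the requested components.
#'   `"bernoulli"`: each season is an independent Bernoulli(`pi`) draw, which
#'   adds binomial variance `pi (1 - pi) / 6` on top of `var_residual`.
#' @param recording_rate Fraction of eligible females (known parents, born
#'   early enough to complete a career) that are given recorded careers.
#' @param seed Integer seed; identical configurations and seeds reproduce the
#'   generated tables exactly.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_pedigree()], [simulate_careers()]
#' @export
sim_config <- function(n_founders = 500L,
                       n_generations = 12L,
                       n_recorded_mares_target = 3000L,
                       sires_per_generation = 55L,
                       eu_count = 9L,
                       birth_year_range = c(1993L, 2015L),
                       p_first_foaling_age3 = 0.42,
                       var_herd = 0.141e-3,
                       var_additive = 4.848e-3,
                       var_dominance = 1.628e-3,
                       var_residual = 13.426e-3,
                       inbreeding_depression_slope = -0.25,
                       mean_lfr_liability = 0.700,
                       career_length_distribution = c(`3` = 0.16, `4` = 0.16,
                                                      `5` = 0.16, `6` = 0.52),
                       af4_effect = -0.02,
                       abortion_share = 0.15,
                       residual_shape = c("left-skewed", "gaussian"),
                       season_model = c("exchangeable", "bernoulli"),
                       recording_rate = 0.95,
                       seed = 1L) {
  season_model <- match.arg(season_model)
  residual_shape <- match.arg(residual_shape)
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_recorded_mares_target = as.integer(n_recorded_mares_target),
    sires_per_generation = as.integer(sires_per_generation),
    eu_count = as.integer(eu_count),
    birth_year_range = as.integer(birth_year_range),
    p_first_foaling_age3 = p_first_foaling_age3,
    var_herd = var_herd, var_additive = var_additive,
    var_dominance = var_dominance, var_residual = var_residual,
    inbreeding_depression_slope = inbreeding_depression_slope,
    mean_lfr_liability = mean_lfr_liability,
    career_length_distribution = career_length_distribution,
    af4_effect = af4_effect,
    abortion_share = abortion_share,
    residual_shape = residual_shape,
    season_model = season_model,
    recording_rate = recording_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  vars <- c("var_herd", "var_additive", "var_dominance", "var_residual")
  for (v in vars)
    if (!is.numeric(cfg[[v]]) || length(cfg[[v]]) != 1L || cfg[[v]] < 0)
      fail("'%s' must be a single non-negative variance", v)
  if (cfg$n_founders < 2L)
    fail("'n_founders' must be at least 2")
  if (cfg$n_generations < 1L)
    fail("'n_generations' must be at least 1")
  probs <- c("p_first_foaling_age3", "abortion_share", "recording_rate",
             "mean_lfr_liability")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      fail("'%s' must lie in [0, 1]", p)
  cl <- cfg$career_length_distribution
  if (length(cl) != 4L || any(cl < 0) || abs(sum(cl) - 1) > 1e-8)
    fail("'career_length_distribution' must be 4 non-negative probabilities over 3..6 seasons summing to 1")
  if (length(cfg$birth_year_range) != 2L ||
      cfg$birth_year_range[2] < cfg$birth_year_range[1])
    fail("'birth_year_range' must be an increasing year interval")
  invisible(cfg)
}
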