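# Synthetic studbook generator: pedigree with known true genetic values,
# then mare reproductive careers drawn from those values.

#' Simulate a multi-generation horse pedigree with known genetic values
#'
#' Builds an acyclic pedigree of discrete offspring cohorts born every two
#' years.  Dams are drawn (one foal per dam and year) from females born 4-10
#' years earlier, sires from a small stallion pool born 4-12 years earlier,
#' producing paternal half-sib family structure and a slow accumulation of
#' inbreeding.  True breeding values follow the additive infinitesimal model:
#' founders are `N(0, var_additive)`; offspring receive the parent average
#' plus a Mendelian sampling deviate with variance
#' `0.5 * (1 - (F_s + F_d) / 2) * var_additive`.  Dominance deviations are
#' drawn independently per animal with variance `var_dominance` (the full
#' family covariance implied by the dominance relationship matrix is not
#' simulated; it is exercised through estimation instead).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"lfr_simped"` with elements
#'   \item{pedigree}{data frame: `animal`, `sire`, `dam` (0 = unknown),
#'     `birth_year`, `sex` ("M"/"F"), `eu_id`, `generation`.}
#'   \item{truth}{data frame: `animal`, `bv` (true breeding value), `dom`
#'     (true dominance deviation), `f` (inbreeding coefficient).}
#'   \item{config}{the configuration used.}
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  y0 <- config$birth_year_range[1]
  G <- config$n_generations
  nf <- config$n_founders

  # Founders: two cohorts before the main range, female-biased (imported
  # broodmares), so the earliest offspring cohorts have dams available.
  n_f1 <- ceiling(nf / 2)
  founders <- data.frame(
    animal = seq_len(nf),
    sire = UNKNOWN_PARENT, dam = UNKNOWN_PARENT,
    birth_year = rep(c(y0 - 4L, y0 - 3L), c(n_f1, nf - n_f1)),
    sex = rep_len(c("F", "M", "F"), nf),     # two-thirds broodmares
    eu_id = sample.int(config$eu_count, nf, replace = TRUE),
    generation = 0L,
    stringsAsFactors = FALSE
  )

  # Cohort sizing: aim so that females of cohorts 1..G-1 with known parents,
  # recorded at recording_rate, hit the recorded-mare target.  Early cohorts
  # are capped by the available dam pool.
  g_rec <- max(1L, G - 1L)
  # The 1.15 factor offsets early cohorts capped by small founder dam pools.
  c_target <- ceiling(1.15 * config$n_recorded_mares_target /
                        (0.5 * config$recording_rate * g_rec))

  ped <- founders
  last_sire <- integer(0)      # dam id -> sire of her previous foal
  for (g in seq_len(G)) {
    yg <- y0 + 2L * (g - 1L)
    pool_d <- ped$animal[ped$sex == "F" &
                           ped$birth_year <= yg - 3L & ped$birth_year >= yg - 10L]
    pool_s <- ped$animal[ped$sex == "M" &
                           ped$birth_year <= yg - 3L & ped$birth_year >= yg - 12L]
    if (length(pool_d) < 1L || length(pool_s) < 1L)
      fail("generation %d has no available parents; increase n_founders", g)
    n_g <- min(c_target, length(pool_d))   # one foal per dam and year
    dams <- sample(pool_d, n_g, replace = FALSE)
    sires_pool <- sample(pool_s, min(config$sires_per_generation,
                                     length(pool_s)), replace = FALSE)
    sires <- sample(sires_pool, n_g, replace = TRUE)
    # Repeat matings: a quarter of returning dams reuse their previous
    # stallion, creating the full-sib groups seen in real studbooks.
    prev <- last_sire[as.character(dams)]
    reuse <- !is.na(prev) & prev %in% pool_s & runif(n_g) < 0.25
    sires[reuse] <- prev[reuse]
    last_sire[as.character(dams)] <- sires
    ids <- max(ped$animal) + seq_len(n_g)
    # Foals are mostly reared in the dam's environmental unit.
    eu_dam <- ped$eu_id[match(dams, ped$animal)]
    migrate <- runif(n_g) < 0.10
    eu <- ifelse(migrate, sample.int(config$eu_count, n_g, replace = TRUE),
                 eu_dam)
    ped <- rbind(ped, data.frame(
      animal = ids, sire = sires, dam = dams, birth_year = yg,
      sex = ifelse(runif(n_g) < 0.5, "F", "M"),
      eu_id = as.integer(eu), generation = g, stringsAsFactors = FALSE
    ))
  }
  rownames(ped) <- NULL

  # Inbreeding of every animal (needed for Mendelian sampling variances).
  f <- compute_inbreeding(ped[, c("animal", "sire", "dam")])

  bv <- numeric(nrow(ped))
  founder_idx <- ped$sire == UNKNOWN_PARENT & ped$dam == UNKNOWN_PARENT
  bv[founder_idx] <- rnorm(sum(founder_idx), 0, sqrt(config$var_additive))
  idx <- order(ped$birth_year, ped$animal)
  for (i in idx) {
    if (founder_idx[i]) next
    s <- ped$sire[i]; d <- ped$dam[i]
    ms_var <- 0.5 * (1 - (f[s] + f[d]) / 2) * config$var_additive
    bv[i] <- 0.5 * (bv[s] + bv[d]) + rnorm(1L, 0, sqrt(ms_var))
  }
  dom <- rnorm(nrow(ped), 0, sqrt(config$var_dominance))

  out <- list(
    pedigree = ped,
    truth = data.frame(animal = ped$animal, bv = bv, dom = dom, f = f),
    config = config
  )
  class(out) <- "lfr_simped"
  out
}

#' @method print lfr_simped
#' @export
print.lfr_simped <- function(x, ...) {
  ped <- x$pedigree
  cat(sprintf("Synthetic pedigree: %d animals (%d founders, %d generations)\n",
              nrow(ped), sum(ped$generation == 0L), max(ped$generation)))
  cat(sprintf("Birth years %d-%d; mean inbreeding %.4f\n",
              min(ped$birth_year), max(ped$birth_year), mean(x$truth$f)))
  invisible(x)
}

#' Simulate mare reproductive careers from a synthetic pedigree
#'
#' Draws a per-mare lifetime foaling probability
#' `pi = mean_lfr_liability + af4_effect * I(age-4 class) +
#' inbreeding_depression_slope * F + herd + bv + dom + residual`, clamped to
#' `[0, 1]`, and converts it into per-season reproductive events (`F` foaling,
#' `A` abortion, `O` open) over the mare's registered career.  Under the
#' default exchangeable season model the six-season foal count is the
#' stochastic rounding of `6 * pi` and foaling seasons are placed uniformly at
#' random; under `season_model = "bernoulli"` seasons are independent
#' Bernoulli(`pi`) draws.
#'
#' @param sim A `"lfr_simped"` object from [simulate_pedigree()], or a
#'   pedigree data frame (then `truth` must be given).
#' @param truth Optional truth table (`animal`, `bv`, `dom`, `f`) aligned with
#'   the pedigree; taken from `sim` when `sim` is an `"lfr_simped"`.
#' @param config A [sim_config()]; taken from `sim` when available.
#' @return A data frame of reproductive events with columns `mare_id`,
#'   `season` (1-based), `event_year`, `event_type` (`F`/`A`/`O`),
#'   `age_months`, `eu_id`, plus attributes:
#'   `truth_careers` (per-mare liability `pi`, true six-season foal count
#'   `foals6_true`, career length, age class) and `herd_effects` (true EU-BY
#'   herd effects).
#' @export
simulate_careers <- function(sim, truth = NULL, config = NULL) {
  if (inherits(sim, "lfr_simped")) {
    ped <- sim$pedigree
    truth <- truth %||% sim$truth
    config <- config %||% sim$config
  } else {
    ped <- sim
  }
  if (is.null(ped) || nrow(ped) == 0L) fail("empty pedigree")
  if (is.null(truth) || is.null(config)) fail("'truth' and 'config' are required")
  if (!all(ped$animal %in% truth$animal))
    fail("pedigree and truth tables are not aligned")
  validate_sim_config(config)
  set.seed(config$seed + 1000003L)

  G <- max(ped$generation %||% 1L)
  eligible <- ped$sex == "F" &
    ped$sire != UNKNOWN_PARENT & ped$dam != UNKNOWN_PARENT &
    (ped$generation %||% 1L) <= max(1L, G - 1L)
  mares <- ped[eligible & runif(nrow(ped)) < config$recording_rate, ]
  if (nrow(mares) == 0L) fail("no eligible recorded mares in pedigree")

  n <- nrow(mares)
  ti <- match(mares$animal, truth$animal)
  lengths <- sample(3:6, n, replace = TRUE,
                    prob = config$career_length_distribution)
  age4 <- runif(n) >= config$p_first_foaling_age3
  age1 <- ifelse(age4,
                 clamp(round(rnorm(n, 49.0, 2.4)), 48, 59),
                 clamp(round(rnorm(n, 36.6, 1.8)), 36, 47))

  eu_by <- paste(mares$eu_id, mares$birth_year, sep = ":")
  lev <- sort(unique(eu_by))
  herd_eff <- setNames(rnorm(length(lev), 0, sqrt(config$var_herd)), lev)

  resid_var <- if (config$season_model == "exchangeable") {
    max(0, config$var_residual - 1 / 216)   # quantization variance of the
  } else config$var_residual                 # stochastically rounded count
  resid <- if (config$residual_shape == "gaussian") {
    rnorm(n, 0, sqrt(resid_var))
  } else {
    # Reflected standardized gamma: a long left tail of subfertile careers
    # around a concentrated healthy mode (mean 0, variance resid_var,
    # skewness -2/sqrt(shape)).
    sh <- 1.5
    -(rgamma(n, shape = sh) - sh) / sqrt(sh) * sqrt(resid_var)
  }

  pi_mare <- clamp(config$mean_lfr_liability +
                     config$af4_effect * age4 +
                     config$inbreeding_depression_slope * truth$f[ti] +
                     herd_eff[eu_by] +
                     truth$bv[ti] + truth$dom[ti] + resid, 0, 1)

  # Six-season foaling pattern per mare (first `length` seasons registered).
  if (config$season_model == "exchangeable") {
    lo <- floor(6 * pi_mare)
    foals6 <- as.integer(lo + rbinom(n, 1L, 6 * pi_mare - lo))
    pattern <- matrix(FALSE, n, 6L)
    for (i in seq_len(n))
      if (foals6[i] > 0L)
        pattern[i, sample.int(6L, foals6[i])] <- TRUE
  } else {
    pattern <- matrix(rbinom(n * 6L, 1L, rep(pi_mare, 6L)) == 1L, n, 6L)
    foals6 <- as.integer(rowSums(pattern))
  }

  # Event rows for registered seasons, with monthly jitter that keeps
  # consecutive-season intervals within 11-13 months.
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lengths[i]
    s <- seq_len(L)
    step <- c(0L, sample(c(-1L, 0L, 1L), L - 1L, replace = TRUE,
                         prob = c(0.2, 0.6, 0.2)))
    months <- age1[i] + 12L * (s - 1L) + cumsum(step)
    foal <- pattern[i, s]
    type <- ifelse(foal, "F",
                   ifelse(runif(L) < config$abortion_share, "A", "O"))
    rows[[i]] <- data.frame(
      mare_id = mares$animal[i], season = s,
      event_year = mares$birth_year[i] + 3L + (age1[i] >= 48L) + (s - 1L),
      event_type = type, age_months = as.integer(months),
      eu_id = mares$eu_id[i], stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL

  attr(events, "truth_careers") <- data.frame(
    mare_id = mares$animal, pi = pi_mare, foals6_true = foals6,
    n_seasons = lengths, af_class = ifelse(age4, 4L, 3L),
    eu_by = eu_by, stringsAsFactors = FALSE
  )
  attr(events, "herd_effects") <- data.frame(
    eu_by = lev, effect = unname(herd_eff), stringsAsFactors = FALSE
  )
  events
}

#' Truncate registered careers to a fixed number of seasons
#'
#' Keeps the first `k` seasons per mare; mares with fewer than `k` registered
#' seasons are dropped.  Used to create known-truth censoring when validating
#' the sixth-season projection on complete careers.
#'
#' @param events Reproductive-event table ([simulate_careers()] or
#'   [read_studbook()] format).
#' @param k Number of seasons to keep; one of 3, 4, 5.
#' @return The truncated event table (the input is not modified).
#' @export
truncate_careers <- function(events, k) {
  if (length(k) != 1L || !k %in% 3:5)
    fail("'k' must be one of 3, 4, 5")
  events <- events[order(events$mare_id, events$event_year), ]
  season <- stats::ave(seq_len(nrow(events)), events$mare_id,
                       FUN = seq_along)
  n_seasons <- stats::ave(season, events$mare_id, FUN = max)
  out <- events[n_seasons >= k & season <= k, ]
  rownames(out) <- NULL
  attr(out, "truth_careers") <- attr(events, "truth_careers")
  out
}
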