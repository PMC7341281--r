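# End-to-end pipeline: simulate (or read) a studbook, edit, fit and validate
# the sixth-season projections, assemble the four LFR expressions, estimate
# genetic parameters per trait, and post-process EBVs.

#' Pipeline configuration
#'
#' Either `simulation` (a [sim_config()]) or both `studbook` and `pedigree`
#' file paths must be supplied.
#'
#' @param simulation Optional [sim_config()] for synthetic data.
#' @param studbook,pedigree Optional CSV paths for real data.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param rules_full,rules_training [editing_rules()] for the full
#'   (min 3 seasons) and training (6 seasons) datasets.
#' @param traits Trait expressions to analyze, subset of
#'   `c("lfr_c", "lfr_e", "arcsine_c", "arcsine_e")`.
#' @param base_year Base birth-year cohort for EBV standardization.
#' @param min_daughters Stallion selection threshold for rank correlations.
#' @param seed Seed controlling every stochastic stage.
#' @param reml_args Extra arguments passed to [lfr_reml()] (e.g. `tol`).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = NULL, studbook = NULL,
                            pedigree = NULL, out_dir = NULL,
                            rules_full = editing_rules(min_seasons = 3L),
                            rules_training = editing_rules(min_seasons = 6L),
                            traits = c("lfr_c", "lfr_e", "arcsine_c",
                                       "arcsine_e"),
                            base_year = 2000L, min_daughters = 9L,
                            seed = 1L, reml_args = list()) {
  sim_mode <- !is.null(simulation)
  file_mode <- !is.null(studbook) && !is.null(pedigree)
  if (sim_mode == file_mode)
    fail("exactly one of a simulation block or studbook+pedigree paths must be given")
  traits <- match.arg(traits, several.ok = TRUE)
  out <- list(simulation = simulation, studbook = studbook,
              pedigree = pedigree, out_dir = out_dir,
              rules_full = rules_full, rules_training = rules_training,
              traits = traits, base_year = as.integer(base_year),
              min_daughters = min_daughters, seed = as.integer(seed),
              reml_args = reml_args)
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `simulation` and
#' the two `rules_*` blocks are passed to [sim_config()] and
#' [editing_rules()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    if (!is.null(y$simulation$career_length_distribution))
      y$simulation$career_length_distribution <-
        unlist(y$simulation$career_length_distribution)
    if (!is.null(y$simulation$birth_year_range))
      y$simulation$birth_year_range <- unlist(y$simulation$birth_year_range)
    y$simulation <- do.call(sim_config, y$simulation)
  }
  for (r in c("rules_full", "rules_training"))
    if (!is.null(y[[r]])) y[[r]] <- do.call(editing_rules, y[[r]])
  do.call(pipeline_config, y)
}

#' Run the full lifetime-foaling-rate study
#'
#' Executes simulate (or read) -> edit -> fit projections -> validate ->
#' assemble phenotypes -> kinship -> REML per trait -> EBV report, writing
#' CSV outputs and a JSON manifest when `out_dir` is set.  Reruns with the
#' same configuration and seed reproduce all numeric outputs exactly.
#'
#' @param config A [pipeline_config()] object.
#' @param verbose Log stage boundaries with record counts?
#' @return List of class `"lfr_pipeline"`: editing reports, validation
#'   statistics, per-trait fits (`fits`), EBV tables, rank-correlation
#'   matrix, genetic trends and the manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("marelife")),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  if (!is.null(config$simulation)) {
    cfg <- config$simulation
    cfg$seed <- config$seed
    sim <- simulate_pedigree(cfg)
    events <- simulate_careers(sim)
    ped <- sim$pedigree
    log_stage("simulated %d animals, %d recorded mares", nrow(ped),
              length(unique(events$mare_id)))
    note("simulate", animals = nrow(ped),
         recorded_mares = length(unique(events$mare_id)))
  } else {
    events <- read_studbook(config$studbook)
    ped <- read_pedigree(config$pedigree)
    log_stage("read %d events for %d mares; pedigree of %d animals",
              nrow(events), length(unique(events$mare_id)), nrow(ped))
    note("read", events = nrow(events), animals = nrow(ped))
  }

  training <- apply_editing(events, ped, config$rules_training)
  full <- apply_editing(events, ped, config$rules_full)
  log_stage("editing: %d training (6 seasons), %d full (>=3 seasons) mares",
            nrow(training), nrow(full))
  note("edit", training = nrow(training), full = nrow(full),
       training_report = as.list(attr(training, "edit_report")),
       full_report = as.list(attr(full, "edit_report")))
  eu_tab <- build_eu_by(full)
  note("eu_by", levels = attr(eu_tab, "n_levels"),
       mean_records = attr(eu_tab, "mean_records"))

  fits_c <- fits_e <- list()
  valid <- list()
  for (k in 3:5) {
    kk <- as.character(k)
    fits_c[[kk]] <- fit_projection(training, "coefficients", k)
    fits_e[[kk]] <- fit_projection(training, "equations", k)
    valid[[paste0("coefficients_", k)]] <-
      validate_projection(training, "coefficients", k)
    valid[[paste0("equations_", k)]] <-
      validate_projection(training, "equations", k)
  }
  vstats <- do.call(rbind, lapply(valid, function(v)
    data.frame(method = v$method, k = v$k, psb = v$psb, mad = v$mad,
               sdr = v$sdr, stringsAsFactors = FALSE)))
  rownames(vstats) <- NULL
  log_stage("projection validation (leave-one-out): %d method x horizon cells",
            nrow(vstats))

  need_dom <- TRUE
  kin <- kinship(ped, dominance = need_dom)
  phen <- assemble_phenotypes(full, fits_c, fits_e, inbreeding = kin$f)
  note("phenotypes", mares = nrow(full),
       actual = sum(full$n_seasons >= 6L),
       projected = sum(full$n_seasons < 6L))
  log_stage("assembled %d phenotype records (4 traits x %d mares)",
            nrow(phen), nrow(full))

  fits <- list(); ebvs <- list(); varcomps <- list()
  for (tr in config$traits) {
    dat <- phen[phen$trait == tr, , drop = FALSE]
    dat$af_class <- factor(dat$af_class)
    fit <- do.call(lfr_reml, c(list(
      value ~ af_class + f_coef, data = dat, pedigree = kin), config$reml_args))
    fits[[tr]] <- fit
    varcomps[[tr]] <- data.frame(trait = tr, t(fit$varcomp),
                                 h2 = fit$h2, se_h2 = fit$se_h2,
                                 aic = fit$aic, converged = fit$converged)
    tab <- ebv_table(fit, ped, full)
    tab <- standardize_ebv(tab, config$base_year,
                           sqrt(fit$varcomp["additive"]))
    ebvs[[tr]] <- tab
    log_stage("trait %s: h2 = %.3f (SE %.3f), AIC %.1f", tr, fit$h2,
              fit$se_h2, fit$aic)
  }
  varcomp_tab <- do.call(rbind, varcomps)
  rownames(varcomp_tab) <- NULL

  # Rank correlations over recorded mares and selected stallions.
  pairs <- utils::combn(config$traits, 2, simplify = FALSE)
  rc <- do.call(rbind, lapply(pairs, function(p) {
    a <- ebvs[[p[1]]]; b <- ebvs[[p[2]]]
    mare_a <- a$std_ebv[a$recorded]
    mare_b <- b$std_ebv[b$recorded]
    st_a <- select_stallions(a, config$min_daughters)
    st_b <- select_stallions(b, config$min_daughters)
    common <- intersect(st_a$animal, st_b$animal)
    data.frame(trait_a = p[1], trait_b = p[2],
               rho_mares = rank_correlation(mare_a, mare_b),
               rho_stallions = if (length(common) >= 3L)
                 rank_correlation(
                   st_a$std_ebv[match(common, st_a$animal)],
                   st_b$std_ebv[match(common, st_b$animal)]) else NA_real_,
               n_stallions = length(common),
               stringsAsFactors = FALSE)
  }))
  note("rank_correlations", pairs = nrow(rc))

  trends <- list()
  for (tr in config$traits) {
    trends[[tr]] <- tryCatch(
      rbind(genetic_trend(ebvs[[tr]], "mares"),
            genetic_trend(ebvs[[tr]], "sires")),
      error = function(e) NULL)
  }

  out <- list(config = config, training = training, full = full,
              eu_by = eu_tab, validation = vstats,
              projection_fits = list(coefficients = fits_c,
                                     equations = fits_e),
              phenotypes = phen, fits = fits, varcomp = varcomp_tab,
              ebvs = ebvs, rank_correlations = rc, trends = trends,
              manifest = manifest)
  class(out) <- "lfr_pipeline"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(df, name)
      write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
    wp(vstats, "validation.csv")
    wp(phen, "phenotypes.csv")
    wp(varcomp_tab, "variance_components.csv")
    for (tr in names(ebvs)) wp(ebvs[[tr]], sprintf("ebv_%s.csv", tr))
    wp(rc, "rank_correlations.csv")
    for (tr in names(trends))
      if (!is.null(trends[[tr]])) wp(trends[[tr]], sprintf("trend_%s.csv", tr))
    manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  log_stage("pipeline complete (%.1f s)",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

#' @method print lfr_pipeline
#' @export
print.lfr_pipeline <- function(x, ...) {
  cat("Lifetime foaling rate pipeline run\n")
  cat(sprintf("  training mares: %d   full-dataset mares: %d (%d projected)\n",
              nrow(x$training), nrow(x$full),
              sum(x$full$n_seasons < 6L)))
  cat("Variance components by trait:\n")
  print(x$varcomp, row.names = FALSE)
  cat("Rank correlations (standardized EBVs):\n")
  print(x$rank_correlations, row.names = FALSE)
  invisible(x)
}
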