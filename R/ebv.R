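# Post-processing of breeding values: standardization to a base cohort,
# progeny-based accuracy, stallion selection, rank correlations, trends.

#' Build an EBV table from a fit and career data
#'
#' Merges BLUP breeding values with pedigree information and, for males,
#' counts recorded daughters (daughters appearing in the career table).
#'
#' @param fit An `"lfr_reml"` fit.
#' @param pedigree Pedigree data frame (`animal`, `sire`, `dam`,
#'   `birth_year`, `sex`).
#' @param careers Career table of recorded mares (defines `recorded` and
#'   daughter counts).
#' @return Data frame: `animal`, `ebv`, `birth_year`, `sex`, `recorded`,
#'   `n_recorded_daughters`.
#' @export
ebv_table <- function(fit, pedigree, careers) {
  e <- ebv(fit)
  idx <- match(pedigree$animal, as.integer(names(e)))
  rec_sires <- table(careers$sire[careers$sire != UNKNOWN_PARENT])
  nd <- as.integer(rec_sires[as.character(pedigree$animal)])
  nd[is.na(nd)] <- 0L
  data.frame(
    animal = pedigree$animal,
    ebv = unname(e[idx]),
    birth_year = pedigree$birth_year,
    sex = pedigree$sex,
    recorded = pedigree$animal %in% careers$mare_id,
    n_recorded_daughters = nd,
    stringsAsFactors = FALSE
  )
}

#' Standardize EBVs to a base birth-year cohort
#'
#' `std = (EBV - mean EBV of recorded mares born in base_year) /
#' genetic_sd`, so the base cohort averages zero and values are expressed in
#' genetic-standard-deviation units.
#'
#' @param ebvs EBV table ([ebv_table()] format).
#' @param base_year Birth year of the reference cohort of recorded mares.
#' @param genetic_sd Genetic standard deviation of the trait (usually
#'   `sqrt` of the estimated additive variance).
#' @return The table with a `std_ebv` column added.
#' @export
standardize_ebv <- function(ebvs, base_year, genetic_sd) {
  if (genetic_sd <= 0) fail("'genetic_sd' must be positive")
  base <- ebvs$recorded & ebvs$birth_year == base_year & ebvs$sex == "F"
  if (!any(base)) {
    yrs <- sort(unique(ebvs$birth_year[ebvs$recorded & ebvs$sex == "F"]))
    fail("no recorded mares born in %s; available cohort years: %s",
         base_year, paste(yrs, collapse = ", "))
  }
  ebvs$std_ebv <- (ebvs$ebv - mean(ebvs$ebv[base])) / genetic_sd
  ebvs
}

#' Accuracy of a progeny-test EBV
#'
#' Classical accuracy of a sire EBV from `n` daughters with one record each
#' (paternal half-sib progeny test):
#' `r = sqrt(n / (n + k))` with `k = (4 - h2) / h2`.
#'
#' @param n_daughters Number of recorded daughters (vectorized).
#' @param h2 Heritability of the trait.
#' @return Accuracy in `[0, 1)`; 0 when `h2 = 0` by convention.
#' @export
accuracy_from_progeny <- function(n_daughters, h2) {
  if (any(n_daughters < 0)) fail("'n_daughters' must be non-negative")
  if (h2 < 0 || h2 > 1) fail("'h2' must lie in [0, 1]")
  if (h2 == 0) return(rep(0, length(n_daughters)))
  k <- (4 - h2) / h2
  sqrt(n_daughters / (n_daughters + k))
}

#' Select stallions for rank-correlation reporting
#'
#' The operational rule keeps stallions with at least `min_daughters`
#' recorded daughters; alternatively a minimum progeny-test accuracy can be
#' requested, which is converted through [accuracy_from_progeny()].
#'
#' @param ebvs EBV table.
#' @param min_daughters Daughter-count threshold (default 9).
#' @param min_accuracy Optional accuracy threshold used instead of the
#'   count rule; requires `h2`.
#' @param h2 Heritability, needed with `min_accuracy`.
#' @return The male subset of `ebvs` satisfying the rule.
#' @export
select_stallions <- function(ebvs, min_daughters = 9L, min_accuracy = NULL,
                             h2 = NULL) {
  males <- ebvs[ebvs$sex == "M", , drop = FALSE]
  keep <- if (!is.null(min_accuracy)) {
    if (is.null(h2)) fail("'h2' is required with 'min_accuracy'")
    accuracy_from_progeny(males$n_recorded_daughters, h2) >= min_accuracy
  } else {
    males$n_recorded_daughters >= min_daughters
  }
  out <- males[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation between two EBV vectors
#'
#' Rank correlation with average ranks for ties.
#'
#' @param ebv_a,ebv_b Aligned numeric vectors.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(ebv_a, ebv_b) {
  if (length(ebv_a) != length(ebv_b) || length(ebv_a) == 0L)
    fail("inputs must be aligned non-empty vectors")
  if (sd(ebv_a) == 0 || sd(ebv_b) == 0)
    fail("rank correlation is undefined for a constant vector")
  cor(ebv_a, ebv_b, method = "spearman")
}

#' Annual genetic trend from standardized EBVs
#'
#' The reference year is the latest birth year whose cohort (recorded mares,
#' or stallion sires of recorded mares) exceeds `min_cohort_size`; the trend
#' is the mean standardized EBV per birth-year cohort over the `window`
#' years ending at the reference year.
#'
#' @param ebvs EBV table with `std_ebv` ([standardize_ebv()]).
#' @param group `"mares"` (recorded females) or `"sires"` (males with at
#'   least one recorded daughter).
#' @param min_cohort_size Cohort-size threshold defining the reference year
#'   (conventionally >100 mares or >15 sires).
#' @param window Number of adjacent years traced back (default 15).
#' @return Data frame `cohort`, `mean_std_ebv`, `n`, `group`.
#' @export
genetic_trend <- function(ebvs, group = c("mares", "sires"),
                          min_cohort_size = NULL, window = 15L) {
  group <- match.arg(group)
  if (is.null(ebvs$std_ebv)) fail("standardize EBVs first (standardize_ebv)")
  sub <- if (group == "mares") {
    ebvs[ebvs$recorded & ebvs$sex == "F", , drop = FALSE]
  } else {
    ebvs[ebvs$sex == "M" & ebvs$n_recorded_daughters > 0L, , drop = FALSE]
  }
  if (is.null(min_cohort_size))
    min_cohort_size <- if (group == "mares") 100L else 15L
  counts <- table(sub$birth_year)
  ok <- counts > min_cohort_size
  if (!any(ok)) {
    msg <- paste(sprintf("%s:%d", names(counts), as.integer(counts)),
                 collapse = ", ")
    fail("no birth year exceeds the %s cohort threshold %d (cohort sizes: %s)",
         group, min_cohort_size, msg)
  }
  ref_year <- max(as.integer(names(counts))[ok])
  years <- (ref_year - window + 1L):ref_year
  sub <- sub[sub$birth_year %in% years, , drop = FALSE]
  agg <- aggregate(std_ebv ~ birth_year, data = sub, FUN = mean)
  nn <- aggregate(std_ebv ~ birth_year, data = sub, FUN = length)
  out <- data.frame(cohort = agg$birth_year,
                    mean_std_ebv = agg$std_ebv,
                    n = nn$std_ebv,
                    group = group,
                    stringsAsFactors = FALSE)
  out[order(out$cohort), ]
}
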