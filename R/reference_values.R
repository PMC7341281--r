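# Published reference estimates for the Italian Heavy Draught Horse
# population, used as generator defaults and as arithmetic cross-checks.

#' Reference variance components for the Italian Heavy Draught Horse
#'
#' Published REML estimates (variances multiplied by 1e3, i.e. on the
#' LFR-proportion scale divided by 1000) for the four expressions of the
#' lifetime foaling rate in the Italian Heavy Draught Horse population:
#' linear LFR from the coefficients (`lfr_c`) and equations (`lfr_e`)
#' projections and their arcsine transformations.  The `lfr_e` column's
#' printed phenotypic variance (19.469) is inconsistent with the sum of its
#' printed components (20.470) in the source report; the column is kept as
#' printed and flagged by `sum_consistent = FALSE`.
#'
#' @return Data frame with one row per trait expression: component estimates
#'   (`herd`, `additive`, `dominance`, `residual`, all x 1e3), the printed
#'   phenotypic variance (`phenotypic`, x 1e3), printed heritability (`h2`)
#'   and its standard error (`se_h2`), printed AIC, and `sum_consistent`.
#' @export
ihdh_reference_components <- function() {
  data.frame(
    trait = c("lfr_c", "lfr_e", "arcsine_c", "arcsine_e"),
    herd = c(0.141, 0.160, 0.259, 0.276),
    additive = c(4.848, 4.693, 8.975, 8.829),
    dominance = c(1.628, 1.358, 2.896, 2.573),
    residual = c(13.426, 14.259, 25.660, 25.463),
    phenotypic = c(20.043, 19.469, 37.790, 37.141),
    h2 = c(0.242, 0.241, 0.238, 0.237),
    se_h2 = c(0.043, 0.042, 0.042, 0.042),
    aic = c(-3290, -3380, -1370, -1424),
    sum_consistent = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
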