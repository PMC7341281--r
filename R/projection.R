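# Projection of foal production at the sixth breeding season from a partial
# career, LFR phenotype construction, and prediction-validation statistics.

#' Fit a sixth-season foal-production predictor on complete careers
#'
#' Two predictors of the foal count after six breeding seasons are supported,
#' both using the foal count after `k` seasons and the age-at-first-foaling
#' (AF) class:
#' \describe{
#'   \item{coefficients}{classical multiplicative projection factors, as used
#'     to extend incomplete production records: within each AF class the
#'     factor `c = sum(foals6) / sum(foals_k)` scales the current foal count
#'     up to the six-season endpoint, `yhat = c * foals_k`.  Mares with zero
#'     foals after `k` seasons cannot be projected multiplicatively and fall
#'     back to the regression fit (recorded in the object);}
#'   \item{equations}{least-squares linear regression of `foals6` on
#'     `foals_k` with an AF-class contrast, i.e. an intercept-bearing
#'     predictor that regresses extreme counts toward the mean.}
#' }
#' With a single AF class in the training data the AF term (contrast or
#' per-class factor) collapses to one level.
#'
#' @param training Career table ([apply_editing()]) of mares with six
#'   registered seasons.
#' @param method `"coefficients"` or `"equations"`.
#' @param k Projection horizon: number of known seasons (3, 4 or 5).
#' @return Object of class `"lfr_projection"`.
#' @export
fit_projection <- function(training, method = c("coefficients", "equations"),
                           k) {
  method <- match.arg(method)
  if (length(k) != 1L || !k %in% 3:5) fail("'k' must be one of 3, 4, 5")
  if (any(training$n_seasons < 6L) || any(is.na(training$f6)))
    fail("all training mares must have 6 registered seasons")
  fkcol <- paste0("f", k)
  df <- data.frame(y = training$f6,
                   fk = training[[fkcol]],
                   af = factor(training$af_class, levels = c(3L, 4L)))
  df$af <- droplevels(df$af)
  two_af <- nlevels(df$af) > 1L
  eq_form <- if (two_af) y ~ fk + af else y ~ fk
  eq_fit <- lm(eq_form, data = df)
  factors <- NULL
  if (method == "coefficients") {
    sums <- aggregate(cbind(y, fk) ~ af, data = df, FUN = sum)
    factors <- setNames(sums$y / sums$fk, as.character(sums$af))
  }
  out <- list(method = method, k = k, factors = factors, eq_fit = eq_fit,
              two_af = two_af,
              af_levels = levels(df$af),
              n_training = nrow(df))
  class(out) <- "lfr_projection"
  out
}

#' @method print lfr_projection
#' @export
print.lfr_projection <- function(x, ...) {
  cat(sprintf("Sixth-season foal projection (%s method, horizon k = %d)\n",
              x$method, x$k))
  cat(sprintf("  trained on %d complete careers (AF classes: %s)\n",
              x$n_training, paste(x$af_levels, collapse = ", ")))
  if (x$method == "coefficients") {
    cat("  projection factors by AF class:\n")
    print(round(x$factors, 4))
  } else {
    print(round(coef(x$eq_fit), 4))
  }
  invisible(x)
}

#' Predict sixth-season foal production for truncated careers
#'
#' Predictions are clamped to `[foals_after(k), 6]`: a mare cannot lose foals
#' she already produced, nor exceed one foal per season.  Fractional
#' predictions are kept (the lifetime foaling rate divides by 6 without
#' rounding).
#'
#' @param career Career table whose mares have exactly `fit$k` registered
#'   seasons.
#' @param fit An `"lfr_projection"` object of matching horizon.
#' @return Numeric vector of predicted foal counts at season 6.
#' @export
project_foals <- function(career, fit) {
  stopifnot(inherits(fit, "lfr_projection"))
  if (any(career$n_seasons != fit$k))
    fail("career horizon mismatch: fit expects exactly %d registered seasons",
         fit$k)
  fk <- career[[paste0("f", fit$k)]]
  newdata <- data.frame(fk = fk,
                        af = factor(career$af_class, levels = c(3L, 4L)))
  if (fit$two_af) newdata$af <- factor(newdata$af, levels = fit$af_levels)
  eq_pred <- as.numeric(predict(fit$eq_fit, newdata = newdata))
  pred <- if (fit$method == "coefficients") {
    cf <- fit$factors[as.character(newdata$af)]
    if (!fit$two_af) cf <- rep(fit$factors[1], length(fk))
    p <- unname(cf) * fk
    # zero-foal mares (and unseen AF classes) have no multiplicative factor
    p[fk == 0 | is.na(p)] <- eq_pred[fk == 0 | is.na(p)]
    p
  } else {
    eq_pred
  }
  clamp(as.numeric(pred), fk, 6)
}

#' Lifetime foaling rate from a six-season foal count
#'
#' @param foals6 Foal count at the six-season endpoint (0-6, fractional
#'   allowed for projected careers).
#' @return `foals6 / 6`, a proportion in `[0, 1]`.
#' @export
compute_lfr <- function(foals6) {
  if (any(is.na(foals6)) || any(foals6 < 0 | foals6 > 6))
    fail("'foals6' must lie in [0, 6]")
  foals6 / 6
}

#' Arcsine transformation of a proportion trait
#'
#' The default is `asin(p)` in radians, the variant whose first two moments
#' match reference descriptive statistics for this trait (delta method:
#' `sd[asin(p)] = sd(p) / sqrt(1 - p^2)`).  The variance-stabilizing
#' `asin(sqrt(p))` form common for binomial proportions is available via
#' `variant = "sqrt"`.
#'
#' @param lfr Proportions in `[0, 1]`.
#' @param variant `"asin"` (default) or `"sqrt"`.
#' @return Radians in `[0, pi/2]`.
#' @export
arcsine_lfr <- function(lfr, variant = c("asin", "sqrt")) {
  variant <- match.arg(variant)
  if (any(is.na(lfr)) || any(lfr < 0 | lfr > 1))
    fail("'lfr' must lie in [0, 1]")
  if (variant == "asin") asin(lfr) else asin(sqrt(lfr))
}

#' Prediction-validation statistics
#'
#' Percentage squared bias `PSB = 100 * sum((y - yhat)^2) / sum(y^2)`, mean
#' absolute deviation of residuals `MAD = sum(|y - yhat|) / n`, and the
#' sample standard deviation of the residuals (SDR).
#'
#' @param actual,predicted Equal-length numeric vectors of actual and
#'   predicted sixth-season foal counts.
#' @param k,method Optional labels stored in the result.
#' @return List of class `"validation_stats"`: `psb`, `mad`, `sdr`, `n`.
#' @export
validation_stats <- function(actual, predicted, k = NA, method = NA) {
  if (length(actual) == 0L || length(actual) != length(predicted))
    fail("'actual' and 'predicted' must be equal-length non-empty vectors")
  if (all(actual == 0))
    fail("PSB is undefined when all actual values are zero")
  r <- actual - predicted
  out <- list(psb = 100 * sum(r^2) / sum(actual^2),
              mad = mean(abs(r)),
              sdr = sd(r),
              n = length(r), k = k, method = method)
  class(out) <- "validation_stats"
  out
}

#' @method print validation_stats
#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("Projection validation (%s, k = %s, n = %d)\n",
              x$method, x$k, x$n))
  cat(sprintf("  PSB %.4f   MAD %.4f   SDR %.4f\n", x$psb, x$mad, x$sdr))
  invisible(x)
}

#' Validate a projection method on complete careers
#'
#' Truncates complete careers to `k` seasons, predicts the sixth-season foal
#' count and compares with the realized count.  By default predictive
#' ability is measured with leave-one-out residuals, available in closed
#' form for both linear predictors (`e_i / (1 - h_ii)` with `h` the hat
#' leverage), so a predictor is never rewarded for fitting the mare it is
#' predicting; `mode = "insample"` uses the raw fitted residuals instead.
#'
#' @param training Career table of mares with 6 registered seasons.
#' @param method `"coefficients"` or `"equations"`.
#' @param k Horizon (3, 4 or 5).
#' @param mode `"loo"` (default) or `"insample"`.
#' @return A `"validation_stats"` object.
#' @export
validate_projection <- function(training,
                                method = c("coefficients", "equations"),
                                k, mode = c("loo", "insample")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  fit <- fit_projection(training, method, k)
  y <- training$f6
  fk <- training[[paste0("f", k)]]
  af <- factor(training$af_class, levels = c(3L, 4L))
  loo_lm <- function(lmfit) {   # leave-one-out predictions of a linear fit
    h <- stats::lm.influence(lmfit, do.coef = FALSE)$hat
    e <- stats::residuals(lmfit)
    as.numeric(fitted(lmfit) - h * e / pmax(1 - h, 1e-12))
  }
  eq_pred <- if (mode == "insample") as.numeric(fitted(fit$eq_fit))
             else loo_lm(fit$eq_fit)
  pred <- if (method == "equations") {
    eq_pred
  } else {
    p <- numeric(length(y))
    for (lev in levels(droplevels(af))) {
      sel <- af == lev
      Sy <- sum(y[sel]); Sf <- sum(fk[sel])
      p[sel] <- if (mode == "insample") fk[sel] * Sy / Sf
                else fk[sel] * (Sy - y[sel]) / (Sf - fk[sel])
    }
    p[fk == 0] <- eq_pred[fk == 0]
    p
  }
  pred <- clamp(pred, fk, 6)
  validation_stats(y, pred, k = k, method = method)
}

#' Assemble the four LFR phenotype expressions for the full dataset
#'
#' Mares with six registered seasons contribute their actual foal count to
#' every trait; mares with 3-5 seasons are projected with the coefficients
#' fit (LFR-C) and the equations fit (LFR-E) of matching horizon.  Arcsine
#' transforms of both complete the four trait expressions.
#'
#' @param careers Full-dataset career table (at least 3 seasons per mare).
#' @param fits_c,fits_e Lists of `"lfr_projection"` fits indexed by horizon
#'   (`fits_c[["3"]]` etc.) for the coefficients and equations methods.
#' @param inbreeding Optional named vector of inbreeding coefficients
#'   (names = animal ids) merged into the table as covariate `f_coef`.
#' @param variant Arcsine variant, see [arcsine_lfr()].
#' @return Long data frame with one row per mare and trait
#'   (`lfr_c`, `lfr_e`, `arcsine_c`, `arcsine_e`): `mare_id`, `trait`,
#'   `value`, `source` (`actual`/`projected`), `af_class`, `eu_by`,
#'   `birth_year`, `f_coef`.
#' @export
assemble_phenotypes <- function(careers, fits_c, fits_e, inbreeding = NULL,
                                variant = "asin") {
  if (any(careers$n_seasons < 3L))
    fail("every mare needs at least 3 registered seasons")
  if (anyDuplicated(careers$mare_id))
    fail("a mare appears more than once in the career table")
  complete <- careers$n_seasons >= 6L
  foals_c <- foals_e <- ifelse(complete, careers$f6, NA_real_)
  for (kk in 3:5) {
    sel <- careers$n_seasons == kk
    if (!any(sel)) next
    sub <- careers[sel, , drop = FALSE]
    foals_c[sel] <- project_foals(sub, fits_c[[as.character(kk)]])
    foals_e[sel] <- project_foals(sub, fits_e[[as.character(kk)]])
  }
  lfr_c <- compute_lfr(foals_c)
  lfr_e <- compute_lfr(foals_e)
  fcov <- if (is.null(inbreeding)) 0
          else unname(inbreeding[as.character(careers$mare_id)])
  base <- data.frame(
    mare_id = careers$mare_id,
    source = ifelse(complete, "actual", "projected"),
    af_class = careers$af_class,
    eu_by = careers$eu_by,
    birth_year = careers$birth_year,
    f_coef = fcov,
    stringsAsFactors = FALSE
  )
  traits <- list(lfr_c = lfr_c, lfr_e = lfr_e,
                 arcsine_c = arcsine_lfr(lfr_c, variant),
                 arcsine_e = arcsine_lfr(lfr_e, variant))
  out <- do.call(rbind, lapply(names(traits), function(tr) {
    b <- base
    b$trait <- tr
    b$value <- traits[[tr]]
    b
  }))
  rownames(out) <- NULL
  out[, c("mare_id", "trait", "value", "source", "af_class", "eu_by",
          "birth_year", "f_coef")]
}
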