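# S3 methods for the fitted animal model.

#' @method print lfr_reml
#' @export
print.lfr_reml <- function(x, digits = 4, ...) {
  cat("Animal model REML fit (lifetime foaling rate)\n")
  cat("  call: ", paste(deparse(x$call), collapse = " "), "\n", sep = "")
  cat(sprintf("  %d records, %d pedigree animals, %s\n", x$n,
              length(x$animal),
              if (x$converged) sprintf("converged in %d iterations", x$n_iterations)
              else sprintf("NOT converged after %d iterations", x$n_iterations)))
  cat("Variance components:\n")
  print(round(x$varcomp, 6))
  cat(sprintf("Phenotypic variance %.6f;  h2 = %.3f (SE %.3f)\n",
              x$var_phenotypic, x$h2, x$se_h2))
  invisible(x)
}

#' Summarize an LFR animal-model fit
#'
#' @param object An `"lfr_reml"` fit.
#' @param ... Unused.
#' @return A `"summary.lfr_reml"` list with the variance-component table
#'   (estimate, sampling SE, proportion of phenotypic variance),
#'   heritability with its standard error, dominance ratio, AIC and the
#'   fixed-effect table.
#' @method summary lfr_reml
#' @export
summary.lfr_reml <- function(object, ...) {
  vc <- object$varcomp
  se <- sqrt(pmax(diag(object$vcov_vc), 0))
  tab <- data.frame(
    component = names(vc),
    estimate = unname(vc),
    se = unname(se),
    proportion = unname(vc) / object$var_phenotypic
  )
  fixed <- NULL
  if (length(object$beta)) {
    bse <- sqrt(diag(as.matrix(object$vcov_beta)))
    fixed <- data.frame(term = names(object$beta),
                        estimate = unname(object$beta),
                        se = unname(bse),
                        z = unname(object$beta) / bse)
  }
  out <- list(varcomp = tab, fixed = fixed, h2 = object$h2,
              se_h2 = object$se_h2,
              dominance_ratio = object$dominance_ratio,
              logLik = object$logLik, aic = object$aic,
              converged = object$converged,
              n = object$n, n_animal = length(object$animal),
              call = object$call)
  class(out) <- "summary.lfr_reml"
  out
}

#' @method print summary.lfr_reml
#' @export
print.summary.lfr_reml <- function(x, digits = 4, ...) {
  cat("Animal model REML fit\n  call: ",
      paste(deparse(x$call), collapse = " "), "\n\n", sep = "")
  cat(sprintf("Records: %d   Pedigree animals: %d   Converged: %s\n",
              x$n, x$n_animal, x$converged))
  cat("\nVariance components:\n")
  print(transform(x$varcomp, estimate = signif(estimate, digits),
                  se = signif(se, digits),
                  proportion = round(proportion, 3)), row.names = FALSE)
  cat(sprintf("\nHeritability: %.3f (SE %.3f)", x$h2, x$se_h2))
  if (is.finite(x$dominance_ratio))
    cat(sprintf("   Dominance ratio: %.3f", x$dominance_ratio))
  cat(sprintf("\nlogLik (REML): %.3f   AIC: %.1f\n", x$logLik, x$aic))
  if (!is.null(x$fixed)) {
    cat("\nFixed effects (GLS):\n")
    print(transform(x$fixed, estimate = signif(estimate, digits),
                    se = signif(se, digits), z = round(z, 2)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.lfr_reml <- function(object, ...) object$beta

#' @export
residuals.lfr_reml <- function(object, ...) object$residuals

#' @export
fitted.lfr_reml <- function(object, ...) object$fitted

#' @export
logLik.lfr_reml <- function(object, ...) {
  structure(object$logLik, df = length(object$varcomp),
            nobs = object$n, class = "logLik")
}

#' Extract breeding values from a fit
#'
#' @param object An `"lfr_reml"` fit.
#' @param ... Unused.
#' @return Named vector of BLUP breeding values for every pedigree animal.
#' @export
ebv <- function(object, ...) UseMethod("ebv")

#' @export
ebv.lfr_reml <- function(object, ...) object$ebv

#' Predicted genetic merit for pedigree animals
#'
#' Returns the BLUP breeding value of the requested animals (all pedigree
#' animals by default), i.e. the model's prediction of transmissible genetic
#' merit on the trait scale.
#'
#' @param object An `"lfr_reml"` fit.
#' @param animals Optional vector of animal ids.
#' @param ... Unused.
#' @export
predict.lfr_reml <- function(object, animals = NULL, ...) {
  if (is.null(object$ebv)) fail("fit has no additive component")
  if (is.null(animals)) return(object$ebv)
  idx <- match(as.character(animals), names(object$ebv))
  if (anyNA(idx)) fail("unknown animal id(s): %s",
                       paste(animals[is.na(idx)], collapse = ", "))
  object$ebv[idx]
}

#' Simulate phenotypes from a fitted animal model
#'
#' Draws new response vectors from the fitted marginal distribution
#' `N(X beta, sum_i s2_i K_i)` over the recorded mares, using the estimated
#' variance components and relationship structures.
#'
#' @param object An `"lfr_reml"` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one row per recorded mare.
#' @export
simulate.lfr_reml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  # Rebuild the marginal covariance from stored structures.
  V <- matrix(0, n, n)
  env <- attr(object, "K_structures")
  if (is.null(env))
    fail("covariance structures are only retained for fits with <= 1500 records")
  for (nm in names(env)) V <- V + object$varcomp[nm] * env[[nm]]
  ch <- chol(V + diag(1e-12, n))
  mu <- if (length(object$beta)) drop(object$X %*% object$beta) else rep(0, n)
  sims <- mu + t(ch) %*% matrix(rnorm(n * nsim), n, nsim)
  out <- as.data.frame(as.matrix(sims))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot an LFR animal-model fit
#'
#' Left panel: restricted log-likelihood across iterations (monotone by
#' construction).  Right panel: distribution of breeding values for recorded
#' mares versus unphenotyped ancestors.
#'
#' @param x An `"lfr_reml"` fit.
#' @param ... Passed to plotting primitives.
#' @export
plot.lfr_reml <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$logl_path) - 1L, x$logl_path, type = "b",
                 xlab = "iteration", ylab = "restricted logL",
                 main = "REML convergence", ...)
  if (!is.null(x$ebv)) {
    rec <- names(x$ebv) %in% as.character(x$id)
    graphics::boxplot(list(recorded = x$ebv[rec], ancestors = x$ebv[!rec]),
                      ylab = "EBV", main = "Breeding values")
  }
  invisible(x)
}
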