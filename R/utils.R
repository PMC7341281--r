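# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp values into an interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample skewness (moment estimator, m3 / m2^(3/2))
#'
#' @param x numeric vector.
#' @return Skewness of `x` (moment estimator; no small-sample correction).
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

#' Sample excess kurtosis (moment estimator, m4 / m2^2 - 3)
#'
#' @param x numeric vector.
#' @return Excess kurtosis of `x` (0 for a normal distribution).
#' @export
kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^4) / m2^2 - 3
}

# stop() with call.=FALSE and sprintf-style formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Unknown-parent code used across all tables
UNKNOWN_PARENT <- 0L
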