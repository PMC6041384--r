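# Internal helpers shared across modules.

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

#' Stationary first-order autoregressive Gaussian noise
#'
#' Draws a length-`n` AR(1) series with lag-1 autocorrelation `rho` and
#' stationary (marginal) standard deviation `sd`. Innovations are scaled by
#' `sqrt(1 - rho^2)` so the marginal variance does not depend on `rho`.
#'
#' @param n number of time points.
#' @param rho lag-1 autocorrelation, `|rho| < 1`.
#' @param sd stationary standard deviation, `>= 0`.
#' @return numeric vector of length `n`.
#' @keywords internal
ar1_noise <- function(n, rho, sd) {
  if (abs(rho) >= 1) stop_invalid("AR(1) coefficient must satisfy |rho| < 1, got %g", rho)
  if (sd < 0) stop_invalid("noise sd must be non-negative")
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x0 <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive", init = x0))
}

# Row-wise log-sum-exp for a matrix.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Derive a reproducible stream of sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}
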