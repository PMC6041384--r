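# Per-word voxel patterns with controlled representational geometry.

#' Simulate per-word voxel patterns with a known similarity structure
#'
#' Constructs a words-by-voxels pattern matrix whose expected pattern
#' correlation matrix is a `signal_weight` mixture of a correlation-scaled
#' copy of the supplied model similarity matrix and the identity:
#' `Sigma = (1 - w) I + w C`, where `C` rescales the model's off-diagonal
#' values linearly into a positive-definite correlation band. The signal
#' component is drawn with an exact sample second moment (rows of an
#' orthonormalized Gaussian basis), so at `signal_weight = 1` and
#' `noise_sd = 0` the realized pattern covariance equals `C` exactly; iid
#' measurement noise of sd `noise_sd` is then added.
#'
#' The attribute `expected_rdm` carries `Sigma` as a brain-kind similarity
#' matrix; its Spearman correlation with the model matrix is exactly 1 at
#' `signal_weight = 1` because the rescaling is strictly increasing.
#'
#' @param word_ids character vector of word identifiers.
#' @param model_matrix a [similarity_matrix()] over the same words.
#' @param signal_weight mixing weight in `[0, 1]`.
#' @param n_voxels number of voxels (must be >= number of words).
#' @param noise_sd sd of additive iid measurement noise.
#' @param seed RNG seed.
#' @param max_offdiag largest off-diagonal correlation of `C` (default 0.7).
#' @return matrix (word x voxel) with attribute `expected_rdm`.
#' @export
simulate_voxel_patterns <- function(word_ids, model_matrix, signal_weight,
                                    n_voxels, noise_sd = 0.1, seed = 1L,
                                    max_offdiag = 0.7) {
  if (signal_weight < 0 || signal_weight > 1) {
    stop_invalid("signal_weight must lie in [0, 1], got %g", signal_weight)
  }
  s <- similarity_values(model_matrix)
  n <- length(word_ids)
  if (nrow(s) != n) stop_invalid("model matrix must match word_ids (%d words)", n)
  if (n_voxels < n) stop_invalid("need at least as many voxels (%d) as words (%d)", n_voxels, n)
  off <- s[lower.tri(s)]
  rng <- range(off)
  cvals <- if (diff(rng) > 0) (off - rng[1]) / diff(rng) * max_offdiag else rep(max_offdiag / 2, length(off))
  C <- diag(n)
  C[lower.tri(C)] <- cvals
  C <- C + t(C) - diag(n)
  # guarantee positive definiteness by shrinking toward the identity
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    a <- (1e-6 - min(ev)) / (1 - min(ev))
    C <- (1 - a) * C + a * diag(n)
  }
  sigma <- (1 - signal_weight) * diag(n) + signal_weight * C
  set.seed(seed)
  z <- matrix(stats::rnorm(n_voxels * n), n_voxels, n)
  q <- qr.Q(qr(z))                       # n_voxels x n, orthonormal columns
  basis <- sqrt(n_voxels) * t(q)         # rows have exact unit second moment
  e <- eigen(sigma, symmetric = TRUE)
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n) %*% t(e$vectors)
  patterns <- root %*% basis
  if (noise_sd > 0) {
    patterns <- patterns + matrix(stats::rnorm(n * n_voxels, 0, noise_sd), n, n_voxels)
  }
  rownames(patterns) <- word_ids
  attr(patterns, "expected_rdm") <- similarity_matrix(sigma, word_ids, kind = "brain")
  patterns
}
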