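# First-level general linear model: canonical HRF, design construction,
# ordinary least squares estimation, t contrasts and per-word beta maps.

#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the canonical haemodynamic response, a difference of two gamma
#' densities (response peak minus a late undershoot), on an arbitrary time
#' grid. The curve is normalized so its maximum on the grid equals 1.
#'
#' @param time_grid non-negative, strictly increasing vector of times (s).
#' @param peak_delay shape of the response gamma (unit rate), so the mode sits
#'   at `peak_delay - 1` seconds; the default 6 places the peak near 5 s.
#' @param undershoot_delay shape of the undershoot gamma; default 16.
#' @param undershoot_ratio relative amplitude of the undershoot; default 1/6.
#' @return numeric vector of responses, peak-normalized to 1.
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 0.1))
#' @export
canonical_hrf <- function(time_grid, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  if (length(time_grid) < 1L || any(time_grid < 0)) {
    stop_invalid("time grid must be non-negative")
  }
  if (length(time_grid) > 1L && any(diff(time_grid) <= 0)) {
    stop_invalid("time grid must be strictly increasing")
  }
  h <- stats::dgamma(time_grid, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(time_grid, shape = undershoot_delay, rate = 1)
  peak <- max(h)
  if (peak <= 0) return(h)
  h / peak
}

#' Build a first-level design matrix from an event table
#'
#' Convolves stimulus events (boxcars of the event duration, or delta sticks)
#' with the canonical HRF on a fine grid and samples the result at the scan
#' times. One regressor is produced per condition (default) or per stimulus
#' id, followed by optional motion columns, an optional linear drift term and
#' an intercept.
#'
#' @param events an event table (see [make_event_schedule()]): columns
#'   `stimulus_id`, `condition`, `onset`, `duration` (and optionally `run`).
#' @param tr repetition time in seconds.
#' @param n_scans number of volumes.
#' @param granularity `"condition"` for one regressor per condition,
#'   `"stimulus"` for one per stimulus id.
#' @param drift add a linear scanner-drift regressor (default `TRUE`).
#' @param motion optional matrix of motion parameters (`n_scans` rows).
#' @param event_model `"boxcar"` (stimulus duration) or `"delta"`.
#' @param dt fine-grid resolution for the convolution, seconds.
#' @return an object of class `design_matrix`: list with `values`
#'   (`n_scans x p`), `regressor_names`, `stimulus_columns` and `tr`.
#' @export
build_design <- function(events, tr, n_scans, granularity = c("condition", "stimulus"),
                         drift = TRUE, motion = NULL,
                         event_model = c("boxcar", "delta"), dt = 0.1) {
  granularity <- match.arg(granularity)
  event_model <- match.arg(event_model)
  validate_events(events)
  total_time <- n_scans * tr
  if (nrow(events) > 0 && any(events$onset + events$duration > total_time)) {
    stop_invalid("event extends beyond the scan window (%g s)", total_time)
  }
  grid <- seq(0, total_time, by = dt)
  hrf <- canonical_hrf(grid[grid <= 32])
  keys <- if (granularity == "condition") {
    as.character(events$condition)
  } else {
    as.character(events$stimulus_id)
  }
  levels_ <- unique(keys)
  scan_times <- (seq_len(n_scans) - 1L) * tr
  cols <- lapply(levels_, function(lv) {
    stick <- numeric(length(grid))
    ev <- events[keys == lv, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      if (event_model == "boxcar") {
        on <- grid >= ev$onset[r] & grid < ev$onset[r] + ev$duration[r]
        stick[on] <- stick[on] + 1
      } else {
        stick[which.min(abs(grid - ev$onset[r]))] <- stick[which.min(abs(grid - ev$onset[r]))] + 1
      }
    }
    conv <- convolve_open(stick, hrf) * dt
    stats::approx(grid, conv[seq_along(grid)], xout = scan_times, rule = 2)$y
  })
  x <- do.call(cbind, cols)
  if (is.null(x)) x <- matrix(numeric(0), nrow = n_scans, ncol = 0)
  nms <- levels_
  stim_cols <- seq_along(levels_)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans) stop_invalid("motion matrix must have %d rows", n_scans)
    x <- cbind(x, motion)
    nms <- c(nms, paste0("motion", seq_len(ncol(motion))))
  }
  if (isTRUE(drift)) {
    x <- cbind(x, seq_len(n_scans) - (n_scans + 1) / 2)
    nms <- c(nms, "drift")
  }
  x <- cbind(x, 1)
  nms <- c(nms, "intercept")
  if (anyDuplicated(nms)) stop_invalid("regressor names must be unique")
  colnames(x) <- nms
  structure(list(values = x, regressor_names = nms,
                 stimulus_columns = stim_cols, tr = tr),
            class = "design_matrix")
}

# Linear ("open") convolution truncated to the length of x.
convolve_open <- function(x, k) {
  out <- stats::convolve(x, rev(k), type = "open")
  out[seq_along(x)]
}

#' Fit an ordinary least squares GLM to one or more time series
#'
#' @param series numeric vector, or matrix with one column per unit
#'   (ROI or voxel) and one row per scan.
#' @param design a `design_matrix` or plain numeric matrix.
#' @return an object of class `glm_fit`: `beta` (regressors x units),
#'   `residual_variance` (per unit), `dof`, `xtx_inv` and regressor names.
#' @export
fit_glm <- function(series, design) {
  x <- design_values(design)
  y <- as.matrix(series)
  if (nrow(y) != nrow(x)) stop_invalid("series has %d scans but design has %d rows", nrow(y), nrow(x))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    stop("degenerate-design error: design matrix is rank deficient", call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  fitted <- x %*% beta
  res <- y - fitted
  dof <- nrow(x) - ncol(x)
  rv <- colSums(res^2) / max(dof, 1L)
  structure(list(beta = beta, residual_variance = rv, dof = dof,
                 xtx_inv = chol2inv(qr.R(qr_x)),
                 regressor_names = colnames(x)),
            class = "glm_fit")
}

design_values <- function(design) {
  if (inherits(design, "design_matrix")) design$values else as.matrix(design)
}

#' t statistic for a linear contrast of GLM coefficients
#'
#' Computes `t = c'beta / sqrt(s2 * c'(X'X)^-1 c)` per unit. A zero residual
#' variance with a non-zero numerator yields a signed infinite statistic
#' (flagged, not an error); 0/0 yields `NaN`.
#'
#' @param fit a `glm_fit`.
#' @param contrast numeric contrast vector, one weight per regressor.
#' @return list with `t` (per unit), `dof` and `unbounded` flag vector.
#' @export
contrast_t <- function(fit, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  p <- nrow(as.matrix(fit$beta))
  if (length(contrast) != p) {
    stop_invalid("contrast has length %d but the fit has %d regressors", length(contrast), p)
  }
  if (all(contrast == 0)) stop_invalid("contrast must not be all zero")
  num <- drop(crossprod(contrast, fit$beta))
  quad <- drop(t(contrast) %*% fit$xtx_inv %*% contrast)
  se <- sqrt(fit$residual_variance * quad)
  t <- ifelse(se > 0, num / se, ifelse(num == 0, NaN, sign(num) * Inf))
  # an (effectively) exact fit makes the statistic unbounded, not astronomical
  huge <- is.finite(t) & abs(t) > 1e8
  t[huge] <- sign(t[huge]) * Inf
  list(t = unname(t), dof = fit$dof, unbounded = unname(!is.finite(t) & !is.nan(t)))
}

#' Per-word activation amplitudes (beta maps)
#'
#' Estimates one amplitude per stimulus id per unit by fitting a
#' stimulus-granularity GLM. With multiple runs (a list of series matrices
#' plus an event table carrying a `run` column) betas are estimated per run
#' and averaged across the runs in which the stimulus occurs.
#'
#' @param series matrix (scans x units) or list of such matrices, one per run.
#' @param events event table; with a `run` column when `series` is a list.
#' @param tr repetition time (s).
#' @param n_scans scans per run.
#' @param ... passed to [build_design()].
#' @return matrix of class `beta_maps` (stimulus x unit), rownames are
#'   stimulus ids.
#' @export
per_word_betas <- function(series, events, tr, n_scans, ...) {
  if (!is.list(series)) {
    series <- list(series)
    events$run <- events$run %||% 1L
  }
  runs <- sort(unique(events$run))
  if (length(runs) != length(series)) {
    stop_invalid("events cover %d runs but %d series matrices were given",
                 length(runs), length(series))
  }
  all_ids <- unique(as.character(events$stimulus_id))
  acc <- matrix(0, length(all_ids), ncol(as.matrix(series[[1]])),
                dimnames = list(all_ids, colnames(as.matrix(series[[1]]))))
  cnt <- integer(length(all_ids))
  for (k in seq_along(runs)) {
    ev <- events[events$run == runs[k], , drop = FALSE]
    ev$onset <- ev$onset  # onsets are run-relative
    des <- build_design(ev, tr, n_scans, granularity = "stimulus", ...)
    fit <- fit_glm(series[[k]], des)
    ids <- des$regressor_names[des$stimulus_columns]
    b <- as.matrix(fit$beta)[des$stimulus_columns, , drop = FALSE]
    i <- match(ids, all_ids)
    acc[i, ] <- acc[i, ] + b
    cnt[i] <- cnt[i] + 1L
  }
  if (any(cnt == 0)) {
    stop_invalid("stimulus id(s) missing from every run: %s",
                 paste(all_ids[cnt == 0], collapse = ", "))
  }
  out <- acc / cnt
  class(out) <- c("beta_maps", class(out))
  out
}

#' Mean-center beta maps across words
#'
#' Subtracts the across-word mean from each unit (column), the standard
#' normalization applied before representational similarity analysis. The
#' operation is idempotent.
#'
#' @param betas matrix (stimulus x unit), e.g. from [per_word_betas()].
#' @return centered matrix with the same dimensions and class.
#' @export
mean_center <- function(betas) {
  m <- as.matrix(betas)
  out <- sweep(m, 2L, colMeans(m), "-")
  class(out) <- class(betas)
  dimnames(out) <- dimnames(m)
  out
}
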