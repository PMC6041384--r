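# Multi-subject Bayesian activation model: ROI neighbor network, spike-and-
# slab amplitudes with an Ising (autologistic) spatial prior and a shared
# truncated stick-breaking amplitude mixture across subjects, Bayesian FDR
# thresholding and hierarchical subject clustering.

#' Build an ROI neighbor network by distance thresholding
#'
#' Computes all pairwise Euclidean distances between ROI centroids and picks
#' the smallest candidate threshold (from the sorted distances) whose induced
#' graph reaches at least the target mean degree; two ROIs are neighbors when
#' their distance is at or below the threshold.
#'
#' @param centroids numeric matrix (ROI x 3) of centroid coordinates in mm,
#'   or a `parcellation`.
#' @param target_mean_degree desired average number of neighbors (e.g. 5).
#' @return object of class `neighbor_network`: boolean `adjacency` (zero
#'   diagonal, symmetric), `threshold_used` (mm) and `mean_degree`.
#' @export
build_neighbor_network <- function(centroids, target_mean_degree = 5) {
  if (inherits(centroids, "parcellation")) {
    centroids <- as.matrix(centroids$roi[, c("x", "y", "z")])
  }
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop_invalid("need at least two ROIs to build a neighbor network")
  if (target_mean_degree <= 0 || target_mean_degree > n - 1) {
    stop_invalid("target_mean_degree must lie in (0, %d]", n - 1)
  }
  d <- as.matrix(stats::dist(centroids))
  dv <- sort(unique(d[upper.tri(d)]))
  n_edges_needed <- ceiling(target_mean_degree * n / 2)
  cum_edges <- vapply(dv, function(t) sum(d[upper.tri(d)] <= t), integer(1))
  k <- which(cum_edges >= n_edges_needed)[1]
  if (is.na(k)) k <- length(dv)
  thr <- dv[k]
  adj <- d <= thr
  diag(adj) <- FALSE
  structure(list(adjacency = adj, threshold_used = thr,
                 mean_degree = mean(rowSums(adj))),
            class = "neighbor_network")
}

#' Activation model hyperparameters
#'
#' @param slab_sd prior sd of the amplitude mixture atoms (default 10,
#'   weakly informative on the scale of percent-signal amplitudes).
#' @param noise_prior inverse-gamma (shape, scale) prior on ROI noise
#'   variance; default `c(2, 1)`.
#' @param mrf_sparsity Ising external field; negative values favour sparse
#'   activation maps a priori (default -2.5).
#' @param mrf_smoothing Ising interaction weight; positive values make
#'   neighboring ROIs co-activate (default 0.5).
#' @param concentration Dirichlet-process concentration of the shared
#'   amplitude mixture (default 1).
#' @param n_iterations total MCMC iterations (default 4000).
#' @param burn_in iterations discarded before summarizing (default 2000).
#' @param seed RNG seed for the chain.
#' @return object of class `activation_model_spec`.
#' @export
activation_model_spec <- function(slab_sd = 10, noise_prior = c(2, 1),
                                  mrf_sparsity = -2.5, mrf_smoothing = 0.5,
                                  concentration = 1, n_iterations = 4000L,
                                  burn_in = 2000L, seed = 1L) {
  if (burn_in >= n_iterations) stop_invalid("burn_in must be smaller than n_iterations")
  if (concentration <= 0) stop_invalid("concentration must be positive")
  if (mrf_smoothing < 0) stop_invalid("mrf_smoothing must be non-negative")
  structure(list(slab_sd = slab_sd, noise_prior = noise_prior,
                 mrf_sparsity = mrf_sparsity, mrf_smoothing = mrf_smoothing,
                 concentration = concentration,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), seed = seed),
            class = "activation_model_spec")
}

#' Fit the multi-subject spike-and-slab activation model
#'
#' Gibbs sampler for a single-stage multi-subject model of ROI time series.
#' For subject i and ROI j, `y_ij = x * gamma_ij * beta_ij + noise`, where the
#' binary activation indicators `gamma` carry an Ising prior on the ROI
#' neighbor network (external field `mrf_sparsity`, interaction
#' `mrf_smoothing`) and active amplitudes are allocated to a discrete mixture
#' of atoms shared across all subjects (truncated stick-breaking with the
#' given concentration), so subjects with similar activation borrow strength
#' from each other. Noise variances are ROI- and subject-specific with an
#' inverse-gamma prior. Nuisance columns of the design (everything except the
#' stimulus regressor) are projected out of both the data and the regressor
#' before sampling.
#'
#' @param series list of subject matrices (scans x ROI), e.g.
#'   `lapply(cohort$series, function(s) s[[1]])` for run 1.
#' @param design a `design_matrix` shared by all subjects.
#' @param spec an [activation_model_spec()].
#' @param network a [build_neighbor_network()] result over the same ROIs.
#' @param stimulus index or name of the stimulus regressor (default: the
#'   design's first stimulus column).
#' @return object of class `posterior_summary`: `activation_probability` and
#'   `beta_mean` (subject x ROI), `sigma2_mean`, and `diagnostics` (trace of
#'   the active fraction and a split-half stability z score).
#' @export
fit_activation_model <- function(series, design, spec, network, stimulus = NULL) {
  stopifnot(inherits(spec, "activation_model_spec"),
            inherits(network, "neighbor_network"))
  x_all <- design_values(design)
  stim_col <- stimulus %||%
    (if (inherits(design, "design_matrix")) design$stimulus_columns[1] else 1L)
  if (is.character(stim_col)) stim_col <- match(stim_col, colnames(x_all))
  x <- x_all[, stim_col]
  nuis <- x_all[, -stim_col, drop = FALSE]
  if (ncol(nuis) == 0) nuis <- matrix(1, nrow(x_all), 1)
  series <- lapply(series, as.matrix)
  n_sub <- length(series)
  n_roi <- ncol(series[[1]])
  if (nrow(network$adjacency) != n_roi) {
    stop_invalid("network covers %d ROIs but series have %d", nrow(network$adjacency), n_roi)
  }
  if (!all(vapply(series, ncol, 1L) == n_roi)) stop_invalid("all subjects must share the ROI set")
  # project out nuisance regressors
  qn <- qr(nuis)
  xr <- qr.resid(qn, x)
  sxx <- sum(xr^2)
  sxy <- matrix(NA_real_, n_sub, n_roi)
  syy <- matrix(NA_real_, n_sub, n_roi)
  for (i in seq_len(n_sub)) {
    yr <- qr.resid(qn, series[[i]])
    sxy[i, ] <- drop(crossprod(xr, yr))
    syy[i, ] <- colSums(yr^2)
  }
  tn <- nrow(x_all) - qr(cbind(nuis, x))$rank
  a0 <- spec$noise_prior[1]; b0 <- spec$noise_prior[2]
  tau2 <- spec$slab_sd^2
  d_field <- spec$mrf_sparsity
  e_int <- spec$mrf_smoothing
  K <- max(n_sub, 5L)
  nbrs <- apply(network$adjacency, 2L, which, simplify = FALSE)

  set.seed(spec$seed)
  sigma2 <- pmax(syy / max(tn, 1L), 1e-8)
  bhat <- if (sxx > 0) sxy / sxx else matrix(0, n_sub, n_roi)
  tstat <- if (sxx > 0) bhat * sqrt(sxx / sigma2) else matrix(0, n_sub, n_roi)
  gamma <- abs(tstat) > 2
  m <- as.numeric(stats::quantile(bhat, probs = seq(0.02, 0.98, length.out = K)))
  m <- m + stats::rnorm(K, 0, 0.01 * max(stats::sd(bhat), 1e-3))
  w <- rep(1 / K, K)
  alloc <- matrix(vapply(as.numeric(bhat), function(b) which.min(abs(m - b)), 1L),
                  n_sub, n_roi)
  keep <- spec$n_iterations - spec$burn_in
  p_acc <- matrix(0, n_sub, n_roi)
  b_acc <- matrix(0, n_sub, n_roi)
  s2_acc <- matrix(0, n_sub, n_roi)
  trace_active <- numeric(spec$n_iterations)

  for (it in seq_len(spec$n_iterations)) {
    logw <- log(pmax(w, 1e-300))
    # --- gamma: one ROI at a time, vectorized over subjects
    for (j in seq_len(n_roi)) {
      nb <- nbrs[[j]]
      nbr_count <- if (length(nb)) rowSums(gamma[, nb, drop = FALSE]) else numeric(n_sub)
      if (sxx > 0) {
        q <- (outer(sxy[, j], m) -
                0.5 * sxx * matrix(m^2, n_sub, K, byrow = TRUE)) / sigma2[, j]
        lse <- row_logsumexp(sweep(q, 2L, logw, "+"))
      } else {
        lse <- 0
      }
      logit <- d_field + e_int * nbr_count + lse
      gamma[, j] <- stats::runif(n_sub) < stats::plogis(logit)
    }
    # --- allocations for active cells (Gumbel-max over atoms)
    act <- which(gamma)
    if (length(act)) {
      if (sxx > 0) {
        q <- (outer(sxy[act], m) -
                0.5 * sxx * matrix(m^2, length(act), K, byrow = TRUE)) / sigma2[act]
      } else {
        q <- matrix(0, length(act), K)
      }
      g <- q + matrix(logw, length(act), K, byrow = TRUE) -
        log(-log(stats::runif(length(act) * K)))
      alloc[act] <- max.col(g)
    }
    # --- atoms: conjugate normal updates from allocated active cells
    prec0 <- 1 / tau2
    prec <- rep(prec0, K)
    mean_num <- numeric(K)
    if (length(act) && sxx > 0) {
      ka <- alloc[act]
      prec <- prec0 + vapply(seq_len(K), function(k) {
        sum(sxx / sigma2[act[ka == k]])
      }, numeric(1))
      mean_num <- vapply(seq_len(K), function(k) {
        sum(sxy[act[ka == k]] / sigma2[act[ka == k]])
      }, numeric(1))
    }
    m <- stats::rnorm(K, mean_num / prec, sqrt(1 / prec))
    # --- stick-breaking weights
    nk <- tabulate(alloc[act], nbins = K)
    n_gt <- rev(cumsum(rev(nk))) - nk
    v <- stats::rbeta(K, 1 + nk, spec$concentration + n_gt)
    v[K] <- 1
    w <- v * cumprod(c(1, 1 - v[-K]))
    # --- noise variances
    bcur <- matrix(0, n_sub, n_roi)
    if (length(act)) bcur[act] <- m[alloc[act]]
    bcur[!gamma] <- 0
    rss <- syy - 2 * bcur * sxy + bcur^2 * sxx
    rss <- pmax(rss, 1e-12)
    sigma2 <- 1 / stats::rgamma(n_sub * n_roi, a0 + tn / 2, b0 + rss / 2)
    sigma2 <- matrix(sigma2, n_sub, n_roi)
    trace_active[it] <- mean(gamma)
    if (it > spec$burn_in) {
      p_acc <- p_acc + gamma
      b_acc <- b_acc + bcur
      s2_acc <- s2_acc + sigma2
    }
  }
  post <- trace_active[(spec$burn_in + 1):spec$n_iterations]
  half <- length(post) %/% 2
  z <- if (half > 1 && stats::sd(post) > 0) {
    (mean(post[seq_len(half)]) - mean(post[(half + 1):length(post)])) /
      (stats::sd(post) / sqrt(half))
  } else 0
  dimnames(p_acc) <- list(names(series), colnames(series[[1]]))
  structure(list(activation_probability = p_acc / keep,
                 beta_mean = b_acc / keep,
                 sigma2_mean = s2_acc / keep,
                 diagnostics = list(trace_active_fraction = trace_active,
                                    split_half_z = z,
                                    converged = abs(z) < 5),
                 spec = spec),
            class = "posterior_summary")
}

#' Bayesian false discovery rate thresholding
#'
#' Sorts posterior activation probabilities in decreasing order and declares
#' the largest prefix whose mean posterior error probability (one minus the
#' activation probability) is at most `alpha`.
#'
#' @param activation_probability numeric vector, matrix or array of posterior
#'   probabilities in `[0, 1]`.
#' @param alpha target Bayesian FDR in `(0, 1)`.
#' @return logical object of the same shape (`TRUE` = declared active) with
#'   attribute `n_declared`.
#' @export
bfdr_threshold <- function(activation_probability, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  p <- activation_probability
  sel <- rep(FALSE, length(p))
  if (length(p)) {
    ord <- order(as.numeric(p), decreasing = TRUE)
    err <- cumsum(1 - as.numeric(p)[ord]) / seq_along(ord)
    n_keep <- if (any(err <= alpha)) max(which(err <= alpha)) else 0L
    if (n_keep > 0) sel[ord[seq_len(n_keep)]] <- TRUE
  }
  out <- sel
  if (!is.null(dim(p))) dim(out) <- dim(p)
  dimnames(out) <- dimnames(p)
  attr(out, "n_declared") <- sum(sel)
  out
}

#' Hierarchical clustering of subjects on thresholded activation amplitudes
#'
#' Agglomerative clustering (average linkage by default) on Euclidean
#' distances between the subjects' feature vectors, typically posterior mean
#' amplitudes zeroed outside the BFDR-declared active set.
#'
#' @param features numeric matrix (subject x ROI).
#' @param linkage `hclust` method, default `"average"`.
#' @return object of class `subject_clustering`: `hclust` tree,
#'   `assignments` matrix (subject x k for k = 1..n-1), `degenerate` flag.
#' @export
cluster_subjects <- function(features, linkage = "average") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop_invalid("need at least two subjects to cluster")
  d <- stats::dist(features)
  hc <- stats::hclust(d, method = linkage)
  ks <- seq_len(n - 1)
  assignments <- sapply(ks, function(k) stats::cutree(hc, k = k))
  colnames(assignments) <- paste0("k", ks)
  degenerate <- all(hc$height < .Machine$double.eps^0.5)
  structure(list(hclust = hc, dist = d, assignments = assignments,
                 degenerate = degenerate),
            class = "subject_clustering")
}

#' Select the number of subject clusters
#'
#' Picks the k maximizing the average silhouette width over the candidate
#' range, reporting within-cluster sums of squares alongside for the elbow
#' diagnostic. Silhouette widths of singleton clusters are 0 by convention.
#' Degenerate clusterings (all pairwise distances zero) return k = 1 with a
#' flag.
#'
#' @param clustering a [cluster_subjects()] result.
#' @param features the feature matrix that was clustered.
#' @param k_range candidate numbers of clusters (default 2..min(n-1, 10)).
#' @return list with `k`, `avg_silhouette` (named by k), `wss`, `degenerate`.
#' @export
select_k <- function(clustering, features, k_range = NULL) {
  stopifnot(inherits(clustering, "subject_clustering"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (clustering$degenerate) {
    return(list(k = 1L, avg_silhouette = NULL, wss = NULL, degenerate = TRUE))
  }
  k_range <- k_range %||% seq(2L, max(2L, min(n - 1L, 10L)))
  d <- clustering$dist
  sil <- vapply(k_range, function(k) {
    cl <- clustering$assignments[, paste0("k", k)]
    s <- cluster::silhouette(cl, d)
    if (length(s) == 1 && is.na(s)) return(NA_real_)
    mean(s[, "sil_width"])
  }, numeric(1))
  wss <- vapply(k_range, function(k) {
    cl <- clustering$assignments[, paste0("k", k)]
    sum(vapply(unique(cl), function(g) {
      sub <- features[cl == g, , drop = FALSE]
      sum(sweep(sub, 2L, colMeans(sub), "-")^2)
    }, numeric(1)))
  }, numeric(1))
  names(sil) <- names(wss) <- k_range
  list(k = k_range[which.max(sil)], avg_silhouette = sil, wss = wss,
       degenerate = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}
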