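# Second-level group contrasts: voxelwise two-sample t maps, connected
# component labeling, cluster-extent thresholding with local maxima, and
# Monte-Carlo calibration of the extent threshold.

#' Second-level group-by-stimulus interaction map
#'
#' Voxelwise pooled-variance two-sample t statistic comparing first-level
#' contrast values (e.g. per-subject pseudoword-vs-word t or beta maps)
#' between two subject groups; dof = n1 + n2 - 2.
#'
#' @param first_level_maps matrix (subject x voxel), or a list of equally
#'   shaped arrays/vectors, one per subject.
#' @param group_labels vector with exactly two groups, each of size >= 2.
#' @return object of class `stat_map`: `values` (with the input's `dim` when
#'   the inputs were arrays), `dof`, `space`.
#' @export
second_level_interaction <- function(first_level_maps, group_labels) {
  dims <- NULL
  if (is.list(first_level_maps)) {
    shapes <- lapply(first_level_maps, function(m) dim(m) %||% length(m))
    if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
      stop_invalid("all first-level maps must share one space (equal dimensions)")
    }
    dims <- dim(first_level_maps[[1]])
    first_level_maps <- do.call(rbind, lapply(first_level_maps, as.numeric))
  }
  m <- as.matrix(first_level_maps)
  gs <- unique(group_labels)
  if (length(gs) != 2) stop_invalid("need exactly two groups, got %d", length(gs))
  i1 <- group_labels == gs[1]; i2 <- group_labels == gs[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop_invalid("each group needs at least two subjects")
  m1 <- colMeans(m[i1, , drop = FALSE]); m2 <- colMeans(m[i2, , drop = FALSE])
  v1 <- apply(m[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(m[i2, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  if (!is.null(dims)) dim(t) <- dims
  structure(list(values = t, dof = n1 + n2 - 2L, space = "voxel",
                 group_order = gs,
                 group_means = list(as.numeric(m1), as.numeric(m2))),
            class = "stat_map")
}

neighbor_offsets <- function(connectivity) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(o)) <= 1,
                 "18" = rowSums(abs(o)) <= 2,
                 "26" = rep(TRUE, nrow(o)),
                 stop_invalid("connectivity must be 6, 18 or 26"))
  o[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first flood fill under 6-, 18- or 26-neighbour connectivity.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array of the same shape; 0 = background, components are
#'   labelled 1, 2, ... in discovery order.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- array(as.logical(mask), dim = dim(mask) %||% c(length(mask), 1L, 1L))
  dims <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, dims)
  todo <- which(mask)
  cur <- 0L
  for (seed in todo) {
    if (lab[seed] > 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      ai <- arrayInd(frontier, dims)
      nb <- ai[rep(seq_len(nrow(ai)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(ai)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * dims[1] * dims[2] + (nb[, 2] - 1L) * dims[1] + nb[, 1])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

#' Cluster-extent thresholding of a statistical map
#'
#' Thresholds the map at the t value of the primary (uncorrected) p,
#' labels connected supra-threshold components, discards components smaller
#' than `extent_k` voxels, and reports each surviving cluster's peak plus up
#' to two further local maxima separated by more than 8 mm (greedy
#' descending-statistic selection). In two-sided mode `|t|` is thresholded;
#' per-group simple-effect directions at the peak voxel are labelled when the
#' map carries group means.
#'
#' @param map a `stat_map` (3D `values`) from [second_level_interaction()],
#'   or a plain 3D array (then supply `dof`).
#' @param primary_p primary uncorrected p threshold (e.g. 0.005).
#' @param extent_k minimum cluster size in voxels (>= 1).
#' @param dof degrees of freedom (taken from the map when available).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param two_sided threshold `|t|` (default `TRUE`).
#' @param voxel_size voxel edge length in mm for reported coordinates.
#' @param min_peak_sep_mm separation required between reported maxima (8 mm).
#' @return data frame of cluster records sorted by size (descending):
#'   `cluster_size`, peak coordinates `peak_x/y/z` (mm), `peak_statistic`,
#'   up to two local maxima coordinate triplets, and per-group direction
#'   labels when available. The voxelwise label array is attached as
#'   attribute `labels`.
#' @export
cluster_extent_threshold <- function(map, primary_p, extent_k, dof = NULL,
                                     connectivity = 26, two_sided = TRUE,
                                     voxel_size = 2, min_peak_sep_mm = 8) {
  if (inherits(map, "stat_map")) {
    vals <- map$values
    dof <- dof %||% map$dof
    gmeans <- map$group_means
  } else {
    vals <- map
    gmeans <- NULL
  }
  if (is.null(dof)) stop_invalid("dof is required")
  if (primary_p <= 0 || primary_p >= 1) stop_invalid("primary_p must lie in (0, 1)")
  if (!is_count(extent_k) || extent_k < 1) stop_invalid("extent_k must be a positive integer")
  if (is.null(dim(vals)) || length(dim(vals)) != 3L) stop_invalid("map values must be a 3D array")
  tcrit <- stats::qt(1 - primary_p, dof)
  mask <- if (two_sided) abs(vals) >= tcrit else vals >= tcrit
  mask[is.na(mask)] <- FALSE
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= extent_k)
  recs <- lapply(keep, function(cl) {
    vox <- which(lab == cl)
    ai <- arrayInd(vox, dim(vals))
    stat <- vals[vox]
    mag <- if (two_sided) abs(stat) else stat
    ord <- order(mag, decreasing = TRUE)
    chosen <- integer(0)
    for (ix in ord) {
      if (length(chosen) >= 3) break
      pos <- ai[ix, ] * voxel_size
      if (all(vapply(chosen, function(cx) {
        sqrt(sum((ai[cx, ] * voxel_size - pos)^2)) > min_peak_sep_mm
      }, logical(1)))) {
        chosen <- c(chosen, ix)
      }
    }
    peak <- chosen[1]
    extras <- chosen[-1]
    coord <- function(ix) (ai[ix, ] - 1) * voxel_size
    pk <- coord(peak)
    out <- data.frame(cluster_size = sizes[cl],
                      peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
                      peak_statistic = stat[peak])
    for (e in 1:2) {
      cc <- if (e <= length(extras)) coord(extras[e]) else c(NA_real_, NA_real_, NA_real_)
      out[[paste0("max", e, "_x")]] <- cc[1]
      out[[paste0("max", e, "_y")]] <- cc[2]
      out[[paste0("max", e, "_z")]] <- cc[3]
    }
    if (!is.null(gmeans)) {
      g1 <- gmeans[[1]][vox[peak]]; g2 <- gmeans[[2]][vox[peak]]
      lab_dir <- function(v) if (abs(v) < 1e-12) "null" else if (v > 0) "positive" else "negative"
      out$direction_group1 <- lab_dir(g1)
      out$direction_group2 <- lab_dir(g2)
    }
    out
  })
  res <- if (length(recs)) do.call(rbind, recs) else data.frame()
  if (nrow(res)) res <- res[order(res$cluster_size, decreasing = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "labels") <- lab
  attr(res, "t_critical") <- tcrit
  res
}

# separable Gaussian smoothing of a 3D array (circular convolution per axis)
smooth_field <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma_vox))
  kern <- stats::dnorm(-half:half, sd = sigma_vox)
  kern <- kern / sum(kern)
  dims <- dim(arr)
  conv_axis <- function(a, axis) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, d[1], d[2] * d[3])
    n <- d[1]
    idx <- outer(seq_len(n), -half:half, "+")
    idx <- ((idx - 1) %% n) + 1
    sm <- matrix(0, n, ncol(m))
    for (k in seq_along(kern)) sm <- sm + kern[k] * m[idx[, k], , drop = FALSE]
    array(sm, d) -> ap2
    aperm(ap2, order(perm))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}

#' Monte-Carlo calibration of the cluster extent threshold
#'
#' Simulates null Gaussian fields with the stated smoothness over the search
#' volume, thresholds each at the primary p (as a z threshold), and returns
#' the smallest extent k such that the proportion of null simulations
#' containing any supra-threshold cluster of at least k voxels does not
#' exceed the family-wise error target.
#'
#' @param volume_dim integer 3-vector, search volume in voxels.
#' @param fwhm_vox smoothness as Gaussian FWHM in voxels (0 = unsmoothed).
#' @param primary_p primary uncorrected threshold.
#' @param fwe target family-wise error rate (e.g. 0.05).
#' @param n_sims number of null simulations (>= 100).
#' @param seed RNG seed.
#' @param connectivity component connectivity (default 26).
#' @return integer extent threshold `k`, with the null distribution of
#'   maximum cluster sizes attached as attribute `max_sizes`.
#' @export
monte_carlo_extent <- function(volume_dim, fwhm_vox, primary_p, fwe = 0.05,
                               n_sims = 1000L, seed = 1L, connectivity = 26) {
  if (n_sims < 100) stop_invalid("n_sims must be at least 100")
  if (primary_p <= 0 || primary_p >= 1) stop_invalid("primary_p must lie in (0, 1)")
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  zcrit <- stats::qnorm(1 - primary_p)
  set.seed(seed)
  max_sizes <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    f <- array(stats::rnorm(prod(volume_dim)), volume_dim)
    f <- smooth_field(f, sigma)
    f <- (f - mean(f)) / stats::sd(f)
    lab <- label_components(f >= zcrit, connectivity)
    max_sizes[s] <- if (any(lab > 0)) max(tabulate(lab[lab > 0])) else 0L
  }
  k <- 1L
  while (mean(max_sizes >= k) > fwe) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}
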