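# Independent oracles used by the test suite. These deliberately re-derive
# quantities by brute force or from definitional formulas, separately from
# the package implementations they check.

# Exhaustive-alignment edit distance: enumerates every alignment recursively.
oracle_edit_distance <- function(sa, sb, ft, indel) {
  sub <- function(p, q) sum(ft[p, ] != ft[q, ])
  rec <- function(i, j) {
    if (i > length(sa) && j > length(sb)) return(0)
    best <- Inf
    if (i <= length(sa)) best <- min(best, indel + rec(i + 1, j))
    if (j <= length(sb)) best <- min(best, indel + rec(i, j + 1))
    if (i <= length(sa) && j <= length(sb)) {
      best <- min(best, sub(sa[i], sb[j]) + rec(i + 1, j + 1))
    }
    best
  }
  rec(1, 1)
}

# Small toy feature inventory: 4 segments x 3 binary features.
toy_inventory <- function() {
  m <- rbind(p = c(0, 0, 0), b = c(1, 0, 0), t = c(0, 1, 0), a = c(1, 1, 1))
  colnames(m) <- c("f1", "f2", "f3")
  m
}

toy_form <- function(id, segs) {
  readerclust::phonological_form(id, segs, toy_inventory())
}

# Definitional tie-corrected Spearman: Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# shift a 3D array by an integer offset, zero-padding
shift_arr <- function(a, o) {
  d <- dim(a)
  out <- array(0, d)
  dst <- lapply(1:3, function(k) seq(max(1, 1 + o[k]), min(d[k], d[k] + o[k])))
  src <- lapply(1:3, function(k) dst[[k]] - o[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Connected-component labeling by iterated minimum-label propagation.
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(offs)) <= 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  lab <- array(seq_along(mask), d)
  lab[!mask] <- 0
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- shift_arr(lab, as.numeric(offs[r, ]))
      upd <- mask & sh > 0 & sh < new
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# two labelings describe the same partition of the masked voxels
same_partition <- function(lab_a, lab_b) {
  va <- lab_a[lab_a > 0 | lab_b > 0]
  vb <- lab_b[lab_a > 0 | lab_b > 0]
  if (any(va == 0) || any(vb == 0)) return(FALSE)
  length(unique(va)) == length(unique(vb)) &&
    nrow(unique(cbind(va, vb))) == length(unique(va))
}

# best-matching assignment overlap between two 2-cluster labelings
cluster_overlap <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  max(mean(a == b), mean(a == (3L - b)))
}

# small noiseless trial table with prescribed condition means
fixed_mean_trials <- function(means = c(word = 588, pseudohomophone = 611,
                                        matched_pseudoword = 598, regular = 492,
                                        irregular = 515, pseudoword = 591),
                              n_subjects = 4) {
  cfg <- readerclust::behavior_config(
    condition_means = means,
    condition_sds = stats::setNames(rep(0, length(means)), names(means)),
    subject_intercept_sd = 0,
    subgroup_sizes = c(n_subjects %/% 2, n_subjects - n_subjects %/% 2),
    p_correct = 1, seed = 1L
  )
  readerclust::simulate_behavior(cfg)
}
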