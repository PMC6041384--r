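# Bayesian multi-subject activation model: neighbor network, sampler,
# BFDR thresholding, subject clustering and cluster-number selection.

test_that("neighbor threshold is the smallest distance reaching the target mean degree", {
  cen <- cbind(c(0, 1, 2, 3), 0, 0)
  net <- build_neighbor_network(cen, target_mean_degree = 1.5)
  expect_equal(net$threshold_used, 1)
  expect_equal(net$mean_degree, 1.5)
  expect_true(net$adjacency[1, 2] && net$adjacency[2, 3] && net$adjacency[3, 4])
  expect_false(net$adjacency[1, 3] || net$adjacency[1, 4])
  expect_true(isSymmetric(net$adjacency))
  expect_true(all(diag(net$adjacency) == FALSE))

  full <- build_neighbor_network(cen, target_mean_degree = 3)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)]))

  expect_error(build_neighbor_network(cen[1, , drop = FALSE], 1), "at least two")
  expect_error(build_neighbor_network(cen, 0), "target_mean_degree")
})

test_that("a 90-ROI carved lattice reaches a realized mean degree in [5, 5.5] at target 5", {
  parc <- make_parcellation(90, c(4, 4, 4), carve = 2, seed = 2)
  net <- build_neighbor_network(parc, target_mean_degree = 5)
  expect_gte(net$mean_degree, 5)
  expect_lte(net$mean_degree, 5.5)
})

test_that("realized mean degree is monotone in the threshold and the choice is minimal", {
  set.seed(8)
  cen <- matrix(stats::rnorm(30 * 3), 30, 3)
  d <- as.matrix(dist(cen))
  dv <- sort(unique(d[upper.tri(d)]))
  degs <- vapply(dv, function(t) mean(rowSums(d <= t) - 1), numeric(1))
  expect_true(all(diff(degs) >= 0))
  net <- build_neighbor_network(cen, 4)
  smaller <- dv[dv < net$threshold_used]
  if (length(smaller)) {
    expect_lt(mean(rowSums(d <= max(smaller)) - 1), 4)
  }
})

test_that("the sampler recovers a high-SNR activation pattern with calibrated probabilities", {
  prof <- matrix(0, 1, 10)
  prof[1, 1:3] <- 1
  cfg <- cohort_config(8, 8, 10, prof, noise_sd = 0.1, n_scans = 140,
                       n_words = 6, n_pseudowords = 2, seed = 3)
  co <- simulate_cohort(cfg)
  parc <- make_parcellation(10, c(3, 3, 3), carve = 2, seed = 2)
  net <- build_neighbor_network(parc, 3)
  spec <- activation_model_spec(n_iterations = 600, burn_in = 300, seed = 11)
  series <- lapply(co$series, function(s) s[[1]])
  post <- fit_activation_model(series, co$designs[[1]], spec, net)
  expect_true(all(post$activation_probability[, 1:3] > 0.95))
  expect_true(all(post$activation_probability[, 4:10] < 0.05))
  expect_true(all(abs(post$beta_mean[, 1:3] - 1) < 0.1))
  # seeded chains reproduce exactly
  post2 <- fit_activation_model(series, co$designs[[1]], spec, net)
  expect_identical(post$activation_probability, post2$activation_probability)
  expect_identical(post$beta_mean, post2$beta_mean)
  # mismatched ROI sets are refused
  expect_error(fit_activation_model(lapply(series, function(s) s[, 1:5]),
                                    co$designs[[1]], spec, net),
               "ROIs")
})

test_that("a null stimulus regressor leaves activation at the prior baseline", {
  parc <- make_parcellation(8, c(3, 3, 3), carve = 2, seed = 4)
  net <- build_neighbor_network(parc, 3)
  for (s in 1:5) {
    set.seed(s)
    series <- lapply(1:4, function(i) matrix(stats::rnorm(60 * 8), 60, 8))
    x <- cbind(stimulus = rep(0, 60), intercept = rep(1, 60))
    spec <- activation_model_spec(n_iterations = 300, burn_in = 150, seed = s)
    post <- fit_activation_model(series, x, spec, net, stimulus = 1)
    expect_true(max(post$activation_probability) < 0.5)
  }
})

test_that("BFDR declares the longest prefix with mean posterior error below alpha", {
  sel <- bfdr_threshold(c(0.999, 0.995, 0.70), alpha = 0.01)
  expect_equal(as.logical(sel), c(TRUE, TRUE, FALSE))
  expect_equal(attr(sel, "n_declared"), 2L)
  expect_true(all(bfdr_threshold(rep(1, 5), alpha = 1e-6)))
  expect_false(any(bfdr_threshold(c(0.9, 0.99, 0.999), alpha = 1e-9)))
  expect_equal(attr(bfdr_threshold(numeric(0), 0.01), "n_declared"), 0L)
  expect_error(bfdr_threshold(c(0.5), alpha = 0), "alpha")
  # matrices keep their shape
  m <- matrix(c(0.99, 0.1, 0.98, 0.2), 2, 2)
  sm <- bfdr_threshold(m, 0.05)
  expect_equal(dim(sm), c(2L, 2L))
})

test_that("the BFDR declared set is non-shrinking in alpha", {
  set.seed(21)
  p <- stats::runif(200)
  prev <- rep(FALSE, 200)
  for (a in c(0.001, 0.01, 0.05, 0.2, 0.5)) {
    cur <- as.logical(bfdr_threshold(p, a))
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("hierarchical clustering separates duplicated profiles and flags degenerate input", {
  feats <- rbind(matrix(0, 3, 4), matrix(10, 4, 4))
  cl <- cluster_subjects(feats)
  expect_equal(unname(cl$assignments[, "k2"]), c(1, 1, 1, 2, 2, 2, 2))
  same <- cluster_subjects(matrix(1, 5, 3))
  expect_true(same$degenerate)
  expect_true(all(same$hclust$height == 0))
  expect_error(cluster_subjects(matrix(1, 1, 3)), "at least two")
})

test_that("line-toy merges join within-triplet pairs before any cross-triplet merge", {
  feats <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), 6, 1)
  cl <- cluster_subjects(feats)
  # first four merge heights stay within-triplet scale, the last crosses
  expect_true(all(cl$hclust$height[1:4] < 1))
  expect_gt(cl$hclust$height[5], 4)
  expect_equal(unname(cl$assignments[, "k2"]), c(1, 1, 1, 2, 2, 2))
})

test_that("silhouette-based selection finds the true number of well-separated blobs", {
  set.seed(10)
  blobs2 <- rbind(matrix(stats::rnorm(10 * 3, 0, 1), 10, 3),
                  matrix(stats::rnorm(20 * 3, 10, 1), 20, 3))
  cl2 <- cluster_subjects(blobs2)
  expect_equal(select_k(cl2, blobs2)$k, 2L)

  centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(10, 17.3, 0))
  blobs3 <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(stats::rnorm(8 * 3, 0, 1), 8, 3), 2, centers[g, ], "+")
  }))
  cl3 <- cluster_subjects(blobs3)
  expect_equal(select_k(cl3, blobs3)$k, 3L)

  degen <- cluster_subjects(matrix(2, 6, 2))
  sel <- select_k(degen, matrix(2, 6, 2))
  expect_true(sel$degenerate)
  expect_equal(sel$k, 1L)
})

test_that("cluster assignments are stable under +/-20% perturbation of the Ising parameters", {
  cfg <- cohort_config(16, c(8, 8), 20,
                       rbind(c(rep(1, 8), rep(0, 12)), c(rep(2.5, 8), rep(1.5, 4), rep(0, 8))),
                       noise_sd = 0.5, n_scans = 120, n_words = 5,
                       n_pseudowords = 3, seed = 6)
  co <- simulate_cohort(cfg)
  parc <- make_parcellation(20, c(3, 3, 3), carve = 2, seed = 3)
  net <- build_neighbor_network(parc, 4)
  series <- lapply(co$series, function(s) s[[1]])
  run_with <- function(sparsity, smoothing) {
    spec <- activation_model_spec(mrf_sparsity = sparsity, mrf_smoothing = smoothing,
                                  n_iterations = 500, burn_in = 250, seed = 9)
    post <- fit_activation_model(series, co$designs[[1]], spec, net)
    feats <- post$beta_mean * bfdr_threshold(post$activation_probability, 0.01)
    cluster_subjects(feats)$assignments[, "k2"]
  }
  base <- run_with(-2.5, 0.5)
  up <- run_with(-2.5 * 1.2, 0.5 * 1.2)
  dn <- run_with(-2.5 * 0.8, 0.5 * 0.8)
  expect_gte(cluster_overlap(base, up), 0.7)
  expect_gte(cluster_overlap(base, dn), 0.7)
})

test_that("adjusted Rand agrees with the reference implementation and bounds", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
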