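# Synthetic cohort generator: parcellation, event schedules, time series,
# voxel patterns and behavioral trials.

test_that("parcellation tiles disjoint cuboid ROIs with lattice centroids", {
  p <- make_parcellation(90, c(4, 4, 4))
  expect_equal(nrow(p$roi), 90)
  vox <- unlist(p$voxel_members)
  expect_length(vox, 90 * 64)
  expect_equal(length(unique(vox)), 90 * 64)  # pairwise disjoint
  expect_false(anyDuplicated(p$roi$roi_id) > 0)

  one <- make_parcellation(1, c(2, 2, 2), voxel_size = 1)
  expect_equal(unlist(one$roi[1, c("x", "y", "z")]), c(x = 1.5, y = 1.5, z = 1.5))

  expect_error(make_parcellation(0), "positive integer")
})

test_that("four single-voxel ROIs on a 2x2x1 grid have hand-enumerable centroid distances", {
  p <- make_parcellation(4, c(1, 1, 1), voxel_size = 1)
  cen <- as.matrix(p$roi[, c("x", "y", "z")])
  d <- as.numeric(dist(cen))
  # grid positions (1,1),(2,1),(1,2),(2,2): four unit edges and two diagonals
  expect_equal(sort(d), sort(c(1, 1, 1, 1, sqrt(2), sqrt(2))))
})

test_that("carved parcellations keep ROIs disjoint but break centroid ties", {
  p <- make_parcellation(90, c(4, 4, 4), carve = 2, seed = 5)
  vox <- unlist(p$voxel_members)
  expect_equal(length(unique(vox)), length(vox))
  expect_true(all(lengths(p$voxel_members) == 62))
  # carving breaks most of the lattice's exact distance ties
  d_carved <- as.numeric(dist(as.matrix(p$roi[, c("x", "y", "z")])))
  d_flat <- as.numeric(dist(as.matrix(make_parcellation(90, c(4, 4, 4))$roi[, c("x", "y", "z")])))
  expect_gt(length(unique(d_carved)), 10 * length(unique(d_flat)))
})

test_that("event schedules respect the onset-asynchrony bounds and are seed-deterministic", {
  ev <- make_event_schedule(30, c(12, 20), 2, seed = 1)
  expect_equal(nrow(ev), 30)
  gaps <- diff(ev$onset)
  expect_true(all(gaps >= 12 & gaps <= 20))
  expect_true(all(ev$duration == 2))

  single <- make_event_schedule(1, c(12, 20), 2, seed = 9, start = 10)
  expect_equal(single$onset, 10)

  expect_identical(make_event_schedule(10, c(12, 20), 2, seed = 7),
                   make_event_schedule(10, c(12, 20), 2, seed = 7))
  expect_error(make_event_schedule(5, c(20, 12), 2), "ordered pair")
  expect_error(make_event_schedule(5, c(1, 3), 2), "duration")
})

test_that("noiseless cohorts equal design times amplitude exactly; the study preset splits 10/20", {
  prof <- matrix(c(1, 0, 0.5, 0, 2, 0), 2, 3, byrow = TRUE)
  cfg <- cohort_config(4, c(2, 2), 3, prof, noise_sd = 0, n_scans = 120,
                       n_words = 4, n_pseudowords = 2)
  co <- simulate_cohort(cfg)
  x <- rowSums(co$designs[[1]]$values[, co$designs[[1]]$stimulus_columns, drop = FALSE])
  for (i in 1:4) {
    expected <- outer(x, prof[co$labels[i], ])
    expect_lt(max(abs(co$series[[i]][[1]] - expected)), 1e-12)
  }
  study <- reading_study_config()
  expect_equal(study$n_subjects, 30)
  expect_equal(study$subgroup_sizes, c(10L, 20L))
  expect_equal(study$n_rois, 90L)
  expect_equal(study$n_scans, 280)
  expect_equal(study$tr, 2)
  co_small <- simulate_cohort(cohort_config(30, c(10, 20), 2,
                                            matrix(0, 2, 2), noise_sd = 0,
                                            n_scans = 120, n_words = 4,
                                            n_pseudowords = 2))
  expect_equal(sum(co_small$labels == 1), 10)
  expect_equal(sum(co_small$labels == 2), 20)
})

test_that("cohort simulation is bitwise deterministic under a fixed seed", {
  cfg <- cohort_config(3, 3, 4, matrix(1, 1, 4), noise_sd = 0.7, n_scans = 90,
                       n_words = 3, n_pseudowords = 2, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$events, b$events)
})

test_that("AR(1) noise reproduces the configured lag-1 autocorrelation and marginal sd", {
  for (rho in c(0.2, 0.5)) {
    r1 <- vapply(1:20, function(s) {
      set.seed(s)
      x <- readerclust:::ar1_noise(10000, rho, 1)
      stats::acf(x, plot = FALSE, lag.max = 1)$acf[2]
    }, numeric(1))
    expect_lt(abs(mean(r1) - rho), 0.02)
  }
  set.seed(1)
  x <- readerclust:::ar1_noise(20000, 0.4, 2)
  expect_lt(abs(sd(x) - 2), 0.1)
})

test_that("identical amplitude profiles yield chance-level subgroup recovery downstream", {
  aris <- vapply(1:20, function(s) {
    prof <- matrix(rep(c(1, 0, 0.5, 0, 1, 0.5, 0, 0), 2), 2, 8, byrow = TRUE)
    cfg <- cohort_config(10, c(5, 5), 8, prof, noise_sd = 1, n_scans = 100,
                         n_words = 4, n_pseudowords = 2, seed = s)
    co <- simulate_cohort(cfg)
    betas <- t(vapply(co$series, function(srs) {
      fit <- fit_glm(srs[[1]], co$designs[[1]])
      stim <- co$designs[[1]]$stimulus_columns
      (fit$beta[stim[1], ] + fit$beta[stim[2], ]) / 2
    }, numeric(8)))
    cl <- cluster_subjects(betas)
    adjusted_rand(cl$assignments[, "k2"], co$labels)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("voxel patterns embed the requested representational geometry", {
  words <- load_stimulus_words()
  words <- words$stimulus_id[words$condition == "word"]
  phon <- phonological_model_matrix(stimulus_phonological_forms(condition = "word"))
  expect_error(simulate_voxel_patterns(words, phon, 1.2, 100), "signal_weight")

  pat <- simulate_voxel_patterns(words, phon, signal_weight = 1, n_voxels = 64,
                                 noise_sd = 0, seed = 3)
  exp_rdm <- attr(pat, "expected_rdm")
  expect_equal(rsa_correlation(exp_rdm, phon), 1)
  # the realized second moment equals the target mixture exactly when noiseless
  sig <- tcrossprod(pat) / 64
  expect_lt(max(abs(sig - exp_rdm$values)), 1e-8)
})

test_that("RSA recovery is near zero without signal and monotone in signal weight", {
  words <- load_stimulus_words()
  ids <- words$stimulus_id[words$condition == "word"]
  phon <- phonological_model_matrix(stimulus_phonological_forms(condition = "word"))
  rsa_at <- function(w, seeds) {
    vapply(seeds, function(s) {
      pat <- simulate_voxel_patterns(ids, phon, w, n_voxels = 200,
                                     noise_sd = 0.3, seed = s)
      rsa_correlation(brain_similarity_matrix(pat), phon)
    }, numeric(1))
  }
  expect_lt(abs(mean(rsa_at(0, 1:50))), 0.05)
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w) mean(rsa_at(w, 1:20)), numeric(1))
  expect_true(all(diff(means) >= -0.01))
  expect_true(means[5] > 0.85)
})

test_that("behavioral generator reproduces configured means and design counts exactly", {
  trials <- fixed_mean_trials()
  cm <- condition_means(trials)
  pooled <- setNames(cm$pooled$mean_rt, cm$pooled$condition)
  expect_equal(pooled[c("word", "pseudohomophone", "matched_pseudoword",
                        "regular", "irregular", "pseudoword")],
               c(word = 588, pseudohomophone = 611, matched_pseudoword = 598,
                 regular = 492, irregular = 515, pseudoword = 591))
  per_subject_counts <- table(trials$condition[trials$subject_id == "sub01"])
  expect_equal(unname(per_subject_counts[c("word", "pseudohomophone", "matched_pseudoword")]),
               c(39L, 39L, 39L), ignore_attr = TRUE)
  expect_equal(unname(per_subject_counts[c("regular", "irregular", "pseudoword")]),
               c(49L, 47L, 30L), ignore_attr = TRUE)
  expect_error(behavior_config(n_trials = c(word = 0L, pseudohomophone = 39L,
                                            matched_pseudoword = 39L, regular = 49L,
                                            irregular = 47L, pseudoword = 30L)),
               "at least one trial")
  cfg <- behavior_config(seed = 3)
  expect_identical(simulate_behavior(cfg), simulate_behavior(cfg))
})

test_that("configured subgroup shifts are recovered in between-group effect differences", {
  # configured effect-shift differences (group1 - group2) under the study preset
  shifts <- rbind(c(-12, -21, -21, -36, -62), c(6, 10, 11, 20, 34))
  colnames(shifts) <- c("pseudohomophone", "matched_pseudoword", "regular",
                        "irregular", "pseudoword")
  conf_ph <- (shifts[1, "pseudohomophone"] - shifts[1, "matched_pseudoword"]) -
    (shifts[2, "pseudohomophone"] - shifts[2, "matched_pseudoword"])
  conf_reg <- (shifts[1, "irregular"] - shifts[1, "regular"]) -
    (shifts[2, "irregular"] - shifts[2, "regular"])
  est <- t(vapply(1:20, function(s) {
    trials <- simulate_behavior(reading_study_behavior_config(seed = s))
    eff <- effect_sizes(condition_means(trials))
    eff <- eff[eff$subject_id != ".pooled", ]
    grp <- trials$subgroup[match(eff$subject_id, trials$subject_id)]
    c(ph = mean(eff$pseudohomophone_effect[grp == 1]) -
        mean(eff$pseudohomophone_effect[grp == 2]),
      reg = mean(eff$regularity_effect[grp == 1]) -
        mean(eff$regularity_effect[grp == 2]))
  }, numeric(2)))
  sem <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, "ph"]) - conf_ph), 2 * sem["ph"] + 1e-9)
  expect_lt(abs(mean(est[, "reg"]) - conf_reg), 2 * sem["reg"] + 1e-9)
})
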