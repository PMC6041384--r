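# Synthetic multi-subject cohort generator: lattice parcellation, event
# schedules with a slow event-related timing, and ROI time series with latent
# reader subgroups and AR(1) noise.

#' Build a synthetic cuboid-block parcellation
#'
#' Tiles a 3D voxel lattice with disjoint cuboid regions of interest (ROIs)
#' arranged on a near-cubic block grid. Centroids are reported in millimetre
#' coordinates (`voxel index * voxel_size`). With `carve > 0`, that many
#' randomly chosen corner voxels are removed from each block; this leaves the
#' regions disjoint and compact but breaks the exact lattice symmetry of the
#' centroids, which is convenient when a distance threshold must be tuned to
#' a fractional mean degree.
#'
#' @param n_rois number of ROIs (>= 1).
#' @param roi_block_shape integer 3-vector, voxels per block along x, y, z.
#' @param voxel_size voxel edge length in mm (default 2).
#' @param carve number of corner voxels to remove per block (default 0).
#' @param seed RNG seed used only when `carve > 0`.
#' @return object of class `parcellation`: `roi` (data frame with `roi_id`,
#'   `roi_name`, centroid `x`, `y`, `z` in mm), `voxel_members` (list of
#'   integer voxel indices into the lattice), `lattice_dim`, `voxel_size`.
#' @export
make_parcellation <- function(n_rois, roi_block_shape = c(4, 4, 4),
                              voxel_size = 2, carve = 0, seed = 1L) {
  if (!is_count(n_rois) || n_rois < 1) stop_invalid("n_rois must be a positive integer")
  if (length(roi_block_shape) != 3L || any(roi_block_shape < 1)) {
    stop_invalid("roi_block_shape must be a positive 3-vector")
  }
  bs <- as.integer(roi_block_shape)
  nx <- ceiling(n_rois^(1 / 3))
  rem <- ceiling(n_rois / nx)
  ny <- ceiling(sqrt(rem))
  nz <- ceiling(rem / ny)
  grid <- expand.grid(gx = seq_len(nx), gy = seq_len(ny), gz = seq_len(nz))
  grid <- grid[seq_len(n_rois), , drop = FALSE]
  lattice_dim <- c(nx, ny, nz) * bs
  set.seed(seed)
  voxel_members <- vector("list", n_rois)
  centroids <- matrix(NA_real_, n_rois, 3)
  block_vox <- expand.grid(vx = seq_len(bs[1]), vy = seq_len(bs[2]), vz = seq_len(bs[3]))
  corner_rows <- which(
    (block_vox$vx %in% c(1L, bs[1])) &
      (block_vox$vy %in% c(1L, bs[2])) &
      (block_vox$vz %in% c(1L, bs[3]))
  )
  for (r in seq_len(n_rois)) {
    off <- (as.integer(grid[r, ]) - 1L) * bs
    vox <- block_vox
    if (carve > 0 && length(corner_rows) > 1L && nrow(vox) > carve) {
      drop_rows <- sample(corner_rows, min(carve, length(corner_rows) - 1L))
      vox <- vox[-drop_rows, , drop = FALSE]
    }
    cx <- vox$vx + off[1]
    cy <- vox$vy + off[2]
    cz <- vox$vz + off[3]
    voxel_members[[r]] <- as.integer(
      (cz - 1L) * lattice_dim[1] * lattice_dim[2] + (cy - 1L) * lattice_dim[1] + cx
    )
    centroids[r, ] <- c(mean(cx), mean(cy), mean(cz)) * voxel_size
  }
  roi <- data.frame(
    roi_id = seq_len(n_rois),
    roi_name = sprintf("ROI%03d", seq_len(n_rois)),
    x = centroids[, 1], y = centroids[, 2], z = centroids[, 3]
  )
  structure(list(roi = roi, voxel_members = voxel_members,
                 lattice_dim = lattice_dim, voxel_size = voxel_size),
            class = "parcellation")
}

#' Generate a slow event-related stimulus schedule
#'
#' Onset gaps are drawn uniformly within `soa_range` (the trial onset
#' asynchrony), emulating a slow event-related design in which single written
#' stimuli are presented for `duration` seconds.
#'
#' @param n_stimuli number of events.
#' @param soa_range length-2 vector, min and max onset asynchrony (s);
#'   `soa_range[1]` must be at least `duration`.
#' @param duration stimulus presentation time (s), default 2.
#' @param seed RNG seed.
#' @param start onset of the first event (s), default 10.
#' @param run run index recorded in the table, default 1.
#' @param stimulus_ids optional character vector of ids (presented in a
#'   seeded random order); defaults to `stim01..stimNN` in order.
#' @param conditions optional per-stimulus condition labels
#'   (`word`/`pseudoword`), aligned with `stimulus_ids`.
#' @return event table (class `event_table`): `stimulus_id`, `condition`,
#'   `onset`, `duration`, `run`.
#' @export
make_event_schedule <- function(n_stimuli, soa_range = c(12, 20), duration = 2,
                                seed = 1L, start = 10, run = 1L,
                                stimulus_ids = NULL, conditions = NULL) {
  if (!is_count(n_stimuli) || n_stimuli < 1) stop_invalid("n_stimuli must be a positive integer")
  if (length(soa_range) != 2L || soa_range[2] < soa_range[1]) {
    stop_invalid("soa_range must be an ordered pair (min <= max)")
  }
  if (soa_range[1] < duration) {
    stop_invalid("minimum onset asynchrony (%g s) must be at least the stimulus duration (%g s)",
                 soa_range[1], duration)
  }
  set.seed(seed)
  gaps <- if (n_stimuli > 1) stats::runif(n_stimuli - 1, soa_range[1], soa_range[2]) else numeric(0)
  onsets <- start + cumsum(c(0, gaps))
  if (is.null(stimulus_ids)) {
    ids <- sprintf("stim%02d", seq_len(n_stimuli))
    conds <- conditions %||% rep("word", n_stimuli)
  } else {
    if (length(stimulus_ids) != n_stimuli) stop_invalid("need %d stimulus ids", n_stimuli)
    ord <- sample.int(n_stimuli)
    ids <- stimulus_ids[ord]
    conds <- (conditions %||% rep("word", n_stimuli))[ord]
  }
  ev <- data.frame(stimulus_id = ids, condition = conds,
                   onset = onsets, duration = duration, run = as.integer(run),
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", class(ev))
  ev
}

validate_events <- function(events) {
  req <- c("stimulus_id", "condition", "onset", "duration")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop_invalid("event table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(events$duration <= 0)) stop_invalid("event durations must be positive")
  runs <- events$run %||% rep(1L, nrow(events))
  for (r in unique(runs)) {
    on <- events$onset[runs == r]
    if (length(on) > 1 && any(diff(on) <= 0)) {
      stop_invalid("onsets must be strictly increasing within run %s", r)
    }
  }
  invisible(events)
}

#' Cohort generator configuration
#'
#' Bundles the design and noise parameters of the synthetic multi-subject
#' cohort. `amplitude_profiles` is a subgroup-by-ROI matrix of true activation
#' amplitudes; subjects inherit the profile of their latent subgroup.
#'
#' @param n_subjects total number of subjects.
#' @param subgroup_sizes integer vector summing to `n_subjects`.
#' @param n_rois number of ROIs.
#' @param amplitude_profiles matrix (`length(subgroup_sizes)` x `n_rois`).
#' @param noise_sd stationary standard deviation of the AR(1) noise.
#' @param ar_coefficient lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param tr repetition time (s).
#' @param n_scans volumes per run.
#' @param soa_range onset asynchrony range (s).
#' @param n_runs number of runs (default 1; the clustering analysis uses a
#'   single run, multi-run designs serve RSA-style validation).
#' @param n_words,n_pseudowords stimuli per run by condition.
#' @param duration stimulus presentation time (s).
#' @param seed master RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, subgroup_sizes, n_rois, amplitude_profiles,
                          noise_sd = 0.5, ar_coefficient = 0.3, tr = 2,
                          n_scans = 280, soa_range = c(12, 20), n_runs = 1L,
                          n_words = 20L, n_pseudowords = 10L, duration = 2,
                          seed = 1L) {
  if (sum(subgroup_sizes) != n_subjects) {
    stop_invalid("subgroup sizes (%s) must sum to n_subjects (%d)",
                 paste(subgroup_sizes, collapse = "+"), n_subjects)
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (abs(ar_coefficient) >= 1) stop_invalid("ar_coefficient must satisfy |rho| < 1")
  amplitude_profiles <- as.matrix(amplitude_profiles)
  if (nrow(amplitude_profiles) != length(subgroup_sizes) ||
      ncol(amplitude_profiles) != n_rois) {
    stop_invalid("amplitude_profiles must be %d x %d", length(subgroup_sizes), n_rois)
  }
  structure(list(n_subjects = n_subjects, subgroup_sizes = subgroup_sizes,
                 n_rois = n_rois, amplitude_profiles = amplitude_profiles,
                 noise_sd = noise_sd, ar_coefficient = ar_coefficient,
                 tr = tr, n_scans = n_scans, soa_range = soa_range,
                 n_runs = as.integer(n_runs), n_words = as.integer(n_words),
                 n_pseudowords = as.integer(n_pseudowords),
                 duration = duration, seed = seed),
            class = "cohort_config")
}

#' Reading-study cohort preset
#'
#' The default study-design conditions: 30 subjects in two latent subgroups of
#' 10 and 20, 90 ROIs, TR 2 s, 280 volumes per run, 30 stimuli per run
#' (20 words, 10 pseudowords) with 12-20 s onset asynchrony. The two
#' subgroups differ by degree, not by double dissociation: both activate a
#' shared set of reading ROIs, the second subgroup with uniformly larger
#' amplitudes plus additional active regions. `dissociated = TRUE` switches
#' to non-overlapping active sets for power studies.
#'
#' @param noise_sd stationary AR(1) noise sd (default 0.5, giving an
#'   amplitude gap of at least three noise sd between subgroups).
#' @param n_runs number of runs (default 1).
#' @param dissociated use disjoint active ROI sets instead of graded profiles.
#' @param seed master RNG seed.
#' @param ... further overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
reading_study_config <- function(noise_sd = 0.5, n_runs = 1L,
                                 dissociated = FALSE, seed = 1L, ...) {
  n_rois <- 90L
  prof <- matrix(0, 2, n_rois)
  if (dissociated) {
    prof[1, 1:20] <- 2
    prof[2, 41:60] <- 2
  } else {
    prof[1, 1:20] <- 1
    prof[2, 1:20] <- 2.5
    prof[2, 21:40] <- 1.5
  }
  cohort_config(n_subjects = 30L, subgroup_sizes = c(10L, 20L), n_rois = n_rois,
                amplitude_profiles = prof, noise_sd = noise_sd, n_runs = n_runs,
                seed = seed, ...)
}

#' Simulate a multi-subject event-related cohort
#'
#' Per subject and run, each ROI time series equals the HRF-convolved
#' stimulus regressor scaled by the subject's subgroup amplitude for that ROI,
#' plus stationary AR(1) Gaussian noise. With `noise_sd = 0` the series equal
#' the design column times the true amplitude exactly.
#'
#' @param config a [cohort_config()].
#' @param events optional event table covering `config$n_runs` runs (a `run`
#'   column partitions it); generated from the config when omitted.
#' @return object of class `cohort_data`: `series[[subject]][[run]]`
#'   (scans x ROI matrices), `events`, latent `labels`, `designs` (per run)
#'   and the `config`.
#' @export
simulate_cohort <- function(config, events = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(config$seed, 2L + config$n_runs + config$n_subjects * config$n_runs)
  if (is.null(events)) {
    n_stim <- config$n_words + config$n_pseudowords
    ids <- c(sprintf("word%02d", seq_len(config$n_words)),
             sprintf("pseudo%02d", seq_len(config$n_pseudowords)))
    conds <- c(rep("word", config$n_words), rep("pseudoword", config$n_pseudowords))
    per_run <- lapply(seq_len(config$n_runs), function(r) {
      make_event_schedule(n_stim, config$soa_range, config$duration,
                          seed = seeds[2L + r], run = r,
                          stimulus_ids = ids, conditions = conds)
    })
    events <- do.call(rbind, per_run)
    class(events) <- c("event_table", "data.frame")
  }
  validate_events(events)
  runs <- sort(unique(events$run %||% 1L))
  designs <- lapply(runs, function(r) {
    ev <- events[(events$run %||% 1L) == r, , drop = FALSE]
    build_design(ev, config$tr, config$n_scans, granularity = "condition",
                 drift = FALSE)
  })
  # single task regressor: sum of all stimulus columns (all stimuli vs baseline)
  task_cols <- lapply(designs, function(d) {
    rowSums(d$values[, d$stimulus_columns, drop = FALSE])
  })
  labels <- rep(seq_along(config$subgroup_sizes), config$subgroup_sizes)
  series <- vector("list", config$n_subjects)
  si <- 0L
  for (i in seq_len(config$n_subjects)) {
    amp <- config$amplitude_profiles[labels[i], ]
    series[[i]] <- vector("list", length(runs))
    for (r in seq_along(runs)) {
      si <- si + 1L
      set.seed(seeds[2L + config$n_runs + si])
      signal <- outer(task_cols[[r]], amp)
      noise <- if (config$noise_sd > 0) {
        vapply(seq_len(config$n_rois), function(j) {
          ar1_noise(config$n_scans, config$ar_coefficient, config$noise_sd)
        }, numeric(config$n_scans))
      } else {
        matrix(0, config$n_scans, config$n_rois)
      }
      m <- signal + noise
      colnames(m) <- sprintf("ROI%03d", seq_len(config$n_rois))
      series[[i]][[r]] <- m
    }
  }
  names(series) <- sprintf("sub%02d", seq_len(config$n_subjects))
  structure(list(series = series, events = events, labels = labels,
                 designs = designs, runs = runs, config = config),
            class = "cohort_data")
}
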