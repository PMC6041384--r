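# Trial-level behavioral data generator: lexical decision and reading aloud.

# condition -> task map used throughout the behavior module
behavior_task_map <- c(
  word = "lexical_decision",
  pseudohomophone = "lexical_decision",
  matched_pseudoword = "lexical_decision",
  regular = "reading_aloud",
  irregular = "reading_aloud",
  pseudoword = "reading_aloud"
)

#' Behavioral generator configuration
#'
#' Defaults reproduce the study conditions: pooled reaction-time means and
#' standard deviations of the lexical decision task (words 588 (61.2),
#' pseudohomophones 611 (74.1), matched pseudowords 598 (73.6) ms) and the
#' reading aloud task (regular 492 (55.9), irregular 515 (62.3), pseudowords
#' 591 (102.4) ms), with 39 items per lexical decision condition and
#' 49/47/30 regular/irregular/pseudoword reading items.
#'
#' `subgroup_shifts` is a subgroup-by-condition matrix of additive RT shifts
#' (ms) encoding latent reader-subgroup differences; the default is zero.
#'
#' @param condition_means named vector of condition mean RTs (ms).
#' @param condition_sds named vector of residual sds (ms).
#' @param n_trials named integer vector of trials per condition (>= 1).
#' @param subject_intercept_sd between-subject intercept sd (ms).
#' @param subgroup_sizes latent subgroup sizes (default `c(10, 20)`).
#' @param subgroup_shifts matrix (`length(subgroup_sizes)` x conditions) of
#'   RT shifts in ms; zero when omitted.
#' @param p_correct probability a trial is answered correctly.
#' @param seed RNG seed.
#' @return object of class `behavior_config`.
#' @export
behavior_config <- function(condition_means = c(word = 588, pseudohomophone = 611,
                                                matched_pseudoword = 598,
                                                regular = 492, irregular = 515,
                                                pseudoword = 591),
                            condition_sds = c(word = 61.2, pseudohomophone = 74.1,
                                              matched_pseudoword = 73.6,
                                              regular = 55.9, irregular = 62.3,
                                              pseudoword = 102.4),
                            n_trials = c(word = 39L, pseudohomophone = 39L,
                                         matched_pseudoword = 39L,
                                         regular = 49L, irregular = 47L,
                                         pseudoword = 30L),
                            subject_intercept_sd = 40,
                            subgroup_sizes = c(10L, 20L),
                            subgroup_shifts = NULL,
                            p_correct = 0.97,
                            seed = 1L) {
  conds <- names(condition_means)
  if (is.null(conds) || !all(conds %in% names(behavior_task_map))) {
    stop_invalid("condition_means must be named with known conditions (%s)",
                 paste(names(behavior_task_map), collapse = ", "))
  }
  if (!all(conds %in% names(condition_sds)) || !all(conds %in% names(n_trials))) {
    stop_invalid("condition_sds and n_trials must cover every condition")
  }
  if (any(condition_sds < 0) || subject_intercept_sd < 0) {
    stop_invalid("standard deviations must be non-negative")
  }
  if (any(n_trials[conds] < 1)) {
    stop_invalid("every condition needs at least one trial; zero requested for %s",
                 paste(conds[n_trials[conds] < 1], collapse = ", "))
  }
  if (is.null(subgroup_shifts)) {
    subgroup_shifts <- matrix(0, length(subgroup_sizes), length(conds),
                              dimnames = list(NULL, conds))
  }
  subgroup_shifts <- as.matrix(subgroup_shifts)
  if (nrow(subgroup_shifts) != length(subgroup_sizes) ||
      !all(conds %in% colnames(subgroup_shifts))) {
    stop_invalid("subgroup_shifts must be subgroups x conditions with condition names")
  }
  structure(list(condition_means = condition_means,
                 condition_sds = condition_sds[conds],
                 n_trials = n_trials[conds],
                 subject_intercept_sd = subject_intercept_sd,
                 subgroup_sizes = subgroup_sizes,
                 subgroup_shifts = subgroup_shifts[, conds, drop = FALSE],
                 p_correct = p_correct, seed = seed),
            class = "behavior_config")
}

#' Reading-study behavioral preset with subgroup effects
#'
#' A [behavior_config()] whose subgroup shifts mirror the observed subgroup
#' condition means: the first (smaller) subgroup is faster overall, most
#' strongly for pseudowords, and carries the larger pseudohomophone effect,
#' while the second subgroup carries the larger lexicality and regularity
#' effects.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [behavior_config()].
#' @export
reading_study_behavior_config <- function(seed = 1L, ...) {
  shifts <- rbind(
    c(word = -13, pseudohomophone = -12, matched_pseudoword = -21,
      regular = -21, irregular = -36, pseudoword = -62),
    c(word = 7, pseudohomophone = 6, matched_pseudoword = 10,
      regular = 11, irregular = 20, pseudoword = 34)
  )
  behavior_config(subgroup_shifts = shifts, seed = seed, ...)
}

#' Simulate trial-level behavioral data
#'
#' Trial RTs are `condition mean + subgroup shift + subject intercept +`
#' Gaussian residual; with all sds and shifts zero, every condition mean
#' equals its configured value exactly.
#'
#' @param config a [behavior_config()].
#' @return trial table (class `trial_table`): `subject_id`, `task`,
#'   `condition`, `rt` (ms), `correct`, `subgroup`.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "behavior_config"))
  set.seed(config$seed)
  n_subjects <- sum(config$subgroup_sizes)
  labels <- rep(seq_along(config$subgroup_sizes), config$subgroup_sizes)
  conds <- names(config$condition_means)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    intercept <- stats::rnorm(1, 0, config$subject_intercept_sd)
    per_cond <- lapply(conds, function(cn) {
      k <- config$n_trials[[cn]]
      rt <- config$condition_means[[cn]] +
        config$subgroup_shifts[labels[i], cn] +
        intercept +
        stats::rnorm(k, 0, config$condition_sds[[cn]])
      data.frame(subject_id = sprintf("sub%02d", i),
                 task = unname(behavior_task_map[cn]),
                 condition = cn,
                 rt = pmax(rt, 1),
                 correct = stats::runif(k) < config$p_correct,
                 subgroup = labels[i],
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_cond)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_table", class(out))
  out
}
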