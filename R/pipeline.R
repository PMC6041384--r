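# End-to-end pipeline driver reproducing the study's analysis order on a
# synthetic cohort: simulate, cluster on the held-out clustering run(s),
# contrast and RSA on the validation runs, behavioral battery, manifest.

#' Pipeline configuration
#'
#' Declares which stages run, how runs are partitioned between clustering and
#' validation, and the per-stage parameter blocks. The run partition is a
#' guard against circular analyses: the run(s) used to cluster subjects must
#' be disjoint from the run(s) used to validate the clusters, and
#' [run_pipeline()] refuses configurations that violate this.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @param stages character subset of
#'   `c("simulate", "cluster", "contrast", "rsa", "behavior")`.
#' @param cohort a [cohort_config()]; defaults to a reduced-size variant of
#'   [reading_study_config()] suitable for interactive use.
#' @param model_spec an [activation_model_spec()].
#' @param behavior a [behavior_config()].
#' @param clustering_runs run indices used for subject clustering (default 1).
#' @param validation_runs run indices for contrast/RSA validation (default:
#'   all other runs).
#' @param target_mean_degree neighbor-network mean degree (default 5).
#' @param bfdr_alpha Bayesian FDR for activation maps (default 0.01).
#' @param rsa_signal_weights per-subgroup phonological signal weights used by
#'   the voxel-pattern simulator in the rsa stage.
#' @param rsa_n_voxels voxels per simulated ROI pattern.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "cluster", "contrast", "rsa", "behavior"),
                            cohort = NULL, model_spec = NULL, behavior = NULL,
                            clustering_runs = 1L, validation_runs = NULL,
                            target_mean_degree = 5, bfdr_alpha = 0.01,
                            rsa_signal_weights = c(0.2, 0.5),
                            rsa_n_voxels = 120L) {
  known <- c("simulate", "cluster", "contrast", "rsa", "behavior")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_invalid("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 cohort = cohort, model_spec = model_spec, behavior = behavior,
                 clustering_runs = as.integer(clustering_runs),
                 validation_runs = if (is.null(validation_runs)) NULL else as.integer(validation_runs),
                 target_mean_degree = target_mean_degree,
                 bfdr_alpha = bfdr_alpha,
                 rsa_signal_weights = rsa_signal_weights,
                 rsa_n_voxels = as.integer(rsa_n_voxels)),
            class = "pipeline_config")
}

#' Run the analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order and writes their outputs
#' and a JSON manifest (seeds, parameters, per-stage products, runs read by
#' each stage) to the output directory. Subject clustering reads only the
#' clustering run(s); contrasts read only the validation run(s). A
#' configuration assigning a run to both is refused.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6L)
  cohort_cfg <- config$cohort %||% reading_study_config(n_runs = 2L, seed = seeds[1])
  validation_runs <- config$validation_runs %||%
    setdiff(seq_len(cohort_cfg$n_runs), config$clustering_runs)
  if (length(intersect(config$clustering_runs, validation_runs))) {
    stop_invalid(paste("run partition violation: run(s) %s assigned to both",
                       "clustering and validation; clustering inputs must be",
                       "disjoint from validation inputs"),
                 paste(intersect(config$clustering_runs, validation_runs), collapse = ", "))
  }
  stages <- config$stages
  manifest <- list(package_version = as.character(utils::packageVersion("readerclust")),
                   seed = config$seed, stage_seeds = as.list(stats::setNames(seeds[1:5],
                     c("simulate", "cluster", "contrast", "rsa", "behavior"))),
                   clustering_runs = config$clustering_runs,
                   validation_runs = validation_runs,
                   stages = stages, runs_read = list(), outputs = list())
  st <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) {
    cohort_cfg$seed <- seeds[1]
    parc <- make_parcellation(cohort_cfg$n_rois, carve = 2, seed = seeds[1])
    st$cohort <- simulate_cohort(cohort_cfg)
    st$parcellation <- parc
    write_events(st$cohort$events, file.path(config$out_dir, "events.tsv"))
    utils::write.csv(data.frame(subject_id = names(st$cohort$series),
                                subgroup = st$cohort$labels),
                     file.path(config$out_dir, "latent_labels.csv"), row.names = FALSE)
    write_timeseries(st$cohort$series[[1]][[1]],
                     file.path(config$out_dir, "roi_series_sub01_run1.csv"))
    manifest$outputs$simulate <- c("events.tsv", "latent_labels.csv",
                                   "roi_series_sub01_run1.csv")
  }

  if ("cluster" %in% stages) {
    if (is.null(st$cohort)) stop_invalid("stage 'cluster' needs output of stage 'simulate'")
    spec <- config$model_spec %||% activation_model_spec(n_iterations = 1200L,
                                                         burn_in = 600L,
                                                         seed = seeds[2])
    run_idx <- match(config$clustering_runs, st$cohort$runs)
    if (anyNA(run_idx)) stop_invalid("clustering run(s) absent from the cohort")
    series1 <- lapply(st$cohort$series, function(s) s[[run_idx[1]]])
    network <- build_neighbor_network(st$parcellation, config$target_mean_degree)
    post <- fit_activation_model(series1, st$cohort$designs[[run_idx[1]]],
                                 spec, network)
    active <- bfdr_threshold(post$activation_probability, config$bfdr_alpha)
    feats <- post$beta_mean * active
    clustering <- cluster_subjects(feats)
    sel <- select_k(clustering, feats)
    k <- sel$k
    st$assignments <- clustering$assignments[, paste0("k", max(k, 1L))]
    if (clustering$degenerate) st$assignments <- rep(1L, nrow(feats))
    st$posterior <- post
    utils::write.csv(data.frame(subject_id = names(st$cohort$series),
                                cluster = st$assignments),
                     file.path(config$out_dir, "cluster_assignments.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(post$activation_probability),
                     file.path(config$out_dir, "activation_probability.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(merge = unclass(clustering$hclust$merge),
           height = clustering$hclust$height,
           order = clustering$hclust$order,
           selected_k = k, avg_silhouette = sel$avg_silhouette, wss = sel$wss),
      file.path(config$out_dir, "dendrogram.json"), auto_unbox = TRUE, digits = NA)
    manifest$runs_read$cluster <- config$clustering_runs
    manifest$outputs$cluster <- c("cluster_assignments.csv",
                                  "activation_probability.csv", "dendrogram.json")
    manifest$selected_k <- k
  }

  if ("contrast" %in% stages) {
    if (is.null(st$cohort)) stop_invalid("stage 'contrast' needs output of stage 'simulate'")
    if (is.null(st$assignments)) stop_invalid("stage 'contrast' needs output of stage 'cluster'")
    if (!length(validation_runs)) stop_invalid("no validation runs available for stage 'contrast'")
    run_idx <- match(validation_runs, st$cohort$runs)
    ev <- st$cohort$events
    subj_maps <- lapply(st$cohort$series, function(s) {
      per_run <- vapply(run_idx, function(ri) {
        evr <- ev[ev$run == st$cohort$runs[ri], , drop = FALSE]
        des <- build_design(evr, st$cohort$config$tr, st$cohort$config$n_scans,
                            granularity = "condition", drift = TRUE)
        fit <- fit_glm(s[[ri]], des)
        cvec <- numeric(length(des$regressor_names))
        cvec[match("pseudoword", des$regressor_names)] <- 1
        cvec[match("word", des$regressor_names)] <- -1
        contrast_t(fit, cvec)$t
      }, numeric(ncol(s[[1]])))
      rowMeans(per_run)
    })
    if (length(unique(st$assignments)) == 2) {
      smap <- second_level_interaction(do.call(rbind, subj_maps), st$assignments)
      utils::write.csv(data.frame(roi = colnames(st$cohort$series[[1]][[1]]),
                                  t = as.numeric(smap$values), dof = smap$dof),
                       file.path(config$out_dir, "group_contrast_roi.csv"), row.names = FALSE)
    } else {
      smap <- NULL
      utils::write.csv(data.frame(note = "second level skipped: need exactly 2 clusters"),
                       file.path(config$out_dir, "group_contrast_roi.csv"), row.names = FALSE)
    }
    manifest$runs_read$contrast <- validation_runs
    manifest$outputs$contrast <- "group_contrast_roi.csv"
  }

  if ("rsa" %in% stages) {
    if (is.null(st$assignments)) stop_invalid("stage 'rsa' needs output of stage 'cluster'")
    words <- load_stimulus_words()
    words <- words[words$condition == "word", , drop = FALSE]
    forms <- stimulus_phonological_forms(condition = "word")
    phon <- phonological_model_matrix(forms)
    sem <- semantic_model_matrix(synthetic_semantic_vectors(words$stimulus_id,
                                                            seed = seeds[4]))
    labels <- st$cohort$labels
    sw <- config$rsa_signal_weights
    sub_seeds <- derive_seeds(seeds[4], length(labels))
    vals <- vapply(seq_along(labels), function(i) {
      pat <- simulate_voxel_patterns(words$stimulus_id, phon,
                                     signal_weight = sw[labels[i]],
                                     n_voxels = config$rsa_n_voxels,
                                     noise_sd = 0.5, seed = sub_seeds[i])
      rsa_correlation(brain_similarity_matrix(mean_center(pat)), phon)
    }, numeric(1))
    res <- data.frame(subject_id = names(st$cohort$series),
                      cluster = st$assignments,
                      phonological_correlation = vals)
    utils::write.csv(res, file.path(config$out_dir, "rsa_results.csv"), row.names = FALSE)
    grp <- group_rsa_test(vals, tail = "greater")
    btw <- if (length(unique(st$assignments)) == 2) {
      between_group_rsa_test(vals, st$assignments)
    } else NULL
    jsonlite::write_json(list(whole_group = grp, between_group = btw,
                              semantic_matrix_written = TRUE),
                         file.path(config$out_dir, "rsa_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    write_similarity(phon, file.path(config$out_dir, "phonological_model.csv"))
    write_similarity(sem, file.path(config$out_dir, "semantic_model.csv"))
    manifest$outputs$rsa <- c("rsa_results.csv", "rsa_tests.json",
                              "phonological_model.csv", "semantic_model.csv")
  }

  if ("behavior" %in% stages) {
    bcfg <- config$behavior %||% reading_study_behavior_config(seed = seeds[5])
    trials <- simulate_behavior(bcfg)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    cm <- condition_means(trials)
    eff <- effect_sizes(cm)
    utils::write.csv(eff, file.path(config$out_dir, "effects.csv"), row.names = FALSE)
    per <- cm$per_subject
    ld <- per[per$condition %in% c("pseudohomophone", "matched_pseudoword"), ]
    groups <- trials$subgroup[match(unique(per$subject_id), trials$subject_id)]
    anova_df <- data.frame(subject_id = ld$subject_id,
                           group = trials$subgroup[match(ld$subject_id, trials$subject_id)],
                           condition = ld$condition, value = ld$mean_rt)
    an <- mixed_anova(anova_df)
    jsonlite::write_json(list(mixed_anova = an,
                              pooled_effects = eff[eff$subject_id == ".pooled", ]),
                         file.path(config$out_dir, "behavior_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs$behavior <- c("trials.csv", "effects.csv", "behavior_report.json")
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
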