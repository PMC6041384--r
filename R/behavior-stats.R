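# Behavioral reading-effect battery: condition means, pseudohomophone /
# lexicality / regularity effects, mixed ANOVA, correlations, t tests.

validate_trials <- function(trials) {
  req <- c("subject_id", "task", "condition", "rt", "correct")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop_invalid("trial table is missing column(s): %s", paste(miss, collapse = ", "))
  bad <- which(trials$rt <= 0)
  if (length(bad)) stop_invalid("non-positive RT at row %d", bad[1])
  badc <- which(behavior_task_map[trials$condition] != trials$task)
  if (length(badc)) {
    stop_invalid("condition '%s' is not valid for task '%s' (row %d)",
                 trials$condition[badc[1]], trials$task[badc[1]], badc[1])
  }
  invisible(trials)
}

#' Per-subject and pooled condition means
#'
#' Mean reaction times and standard deviations per condition, both per
#' subject and pooled over all trials, together with trial and error counts.
#'
#' @param trials a trial table (`subject_id`, `task`, `condition`, `rt`,
#'   `correct`).
#' @param correct_only restrict to correct trials (default `TRUE`).
#' @return list of class `condition_means`: `per_subject` (data frame with
#'   `subject_id`, `task`, `condition`, `mean_rt`, `sd_rt`, `n_trials`,
#'   `missing` flag for empty cells) and `pooled` (per condition).
#' @export
condition_means <- function(trials, correct_only = TRUE) {
  validate_trials(trials)
  used <- if (correct_only) trials[trials$correct, , drop = FALSE] else trials
  subjects <- unique(trials$subject_id)
  conds <- unique(trials$condition)
  grid <- expand.grid(subject_id = subjects, condition = conds,
                      stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    r <- used[used$subject_id == grid$subject_id[i] &
                used$condition == grid$condition[i], , drop = FALSE]
    data.frame(subject_id = grid$subject_id[i],
               task = unname(behavior_task_map[grid$condition[i]]),
               condition = grid$condition[i],
               mean_rt = if (nrow(r)) mean(r$rt) else NA_real_,
               sd_rt = if (nrow(r) > 1) stats::sd(r$rt) else NA_real_,
               n_trials = nrow(r),
               missing = nrow(r) == 0,
               stringsAsFactors = FALSE)
  }))
  pooled <- do.call(rbind, lapply(conds, function(cn) {
    r <- used[used$condition == cn, , drop = FALSE]
    data.frame(condition = cn, task = unname(behavior_task_map[cn]),
               mean_rt = if (nrow(r)) mean(r$rt) else NA_real_,
               sd_rt = if (nrow(r) > 1) stats::sd(r$rt) else NA_real_,
               n_trials = nrow(r), missing = nrow(r) == 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_subject = per, pooled = pooled,
                 correct_only = correct_only),
            class = "condition_means")
}

effect_from_means <- function(df) {
  get1 <- function(cn) {
    v <- df$mean_rt[df$condition == cn]
    if (length(v) == 1 && is.finite(v)) v else NA_real_
  }
  getn <- function(cn) {
    v <- df$n_trials[df$condition == cn]
    if (length(v) == 1) v else 0L
  }
  ph <- get1("pseudohomophone") - get1("matched_pseudoword")
  reg <- get1("irregular") - get1("regular")
  wr <- c(regular = get1("regular"), irregular = get1("irregular"))
  wn <- c(getn("regular"), getn("irregular"))
  word_mean <- if (all(is.finite(wr)) && sum(wn) > 0) {
    sum(wr * wn) / sum(wn)
  } else NA_real_
  lex <- get1("pseudoword") - word_mean
  c(pseudohomophone_effect = ph, lexicality_effect = lex, regularity_effect = reg)
}

#' Reading effect sizes from condition means
#'
#' Computes the three classic effects in milliseconds:
#' * pseudohomophone effect: mean RT to reject pseudohomophones minus matched
#'   pseudowords (lexical decision);
#' * regularity effect: irregular minus regular word naming RT (reading
#'   aloud);
#' * lexicality effect: pseudoword naming RT minus the trial-weighted mean RT
#'   over all word trials (regular and irregular) in reading aloud.
#'
#' Effects whose constituent condition means are missing are returned as
#' `NA`.
#'
#' @param cmeans a [condition_means()] result, or a data frame with columns
#'   `condition`, `mean_rt`, `n_trials` (and optionally `subject_id`).
#' @return data frame of class `effect_summary` with one row per subject
#'   (plus a pooled row when a full `condition_means` object is supplied)
#'   and columns `pseudohomophone_effect`, `lexicality_effect`,
#'   `regularity_effect`.
#' @export
effect_sizes <- function(cmeans) {
  if (inherits(cmeans, "condition_means")) {
    per <- cmeans$per_subject
    subjects <- unique(per$subject_id)
    rows <- do.call(rbind, lapply(subjects, function(s) {
      as.data.frame(as.list(effect_from_means(per[per$subject_id == s, , drop = FALSE])))
    }))
    rows <- cbind(subject_id = subjects, rows)
    pooled <- cbind(subject_id = ".pooled",
                    as.data.frame(as.list(effect_from_means(cmeans$pooled))))
    out <- rbind(rows, pooled)
  } else {
    df <- as.data.frame(cmeans)
    if (is.null(df$n_trials)) df$n_trials <- 1L
    if (is.null(df$subject_id)) df$subject_id <- ".pooled"
    out <- do.call(rbind, lapply(unique(df$subject_id), function(s) {
      cbind(subject_id = s,
            as.data.frame(as.list(effect_from_means(df[df$subject_id == s, , drop = FALSE]))))
    }))
  }
  rownames(out) <- NULL
  class(out) <- c("effect_summary", class(out))
  out
}

#' Two-way mixed-design ANOVA on subject condition means
#'
#' Standard decomposition with one between-subject factor (group) and one
#' within-subject factor (condition), computed on per-subject condition
#' means via `stats::aov` with a subject error stratum. Every subject must
#' contribute every within-subject level.
#'
#' @param data data frame with columns `subject_id`, `group`, `condition`
#'   and `value` (e.g. per-subject mean RTs).
#' @return list with `interaction`, `between`, `within`, each a list of
#'   `F`, `dof` (numerator, denominator) and `p`.
#' @export
mixed_anova <- function(data) {
  req <- c("subject_id", "group", "condition", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop_invalid("mixed_anova needs column(s): %s", paste(miss, collapse = ", "))
  tab <- table(data$subject_id, data$condition)
  if (any(tab != 1)) {
    stop_invalid("every subject must have exactly one value per condition")
  }
  if (length(unique(data$group)) < 2) stop_invalid("need at least two groups")
  d <- data.frame(subject_id = factor(data$subject_id),
                  group = factor(data$group),
                  condition = factor(data$condition),
                  value = data$value)
  fit <- stats::aov(value ~ group * condition + Error(subject_id), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    row <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tb)))
    resid <- grep("Residuals", rownames(tb))
    list(F = tb[row, "F value"],
         dof = c(tb[row, "Df"], tb[resid, "Df"]),
         p = tb[row, "Pr(>F)"])
  }
  list(between = pull("Error: subject_id", "group"),
       within = pull("Error: Within", "condition"),
       interaction = pull("Error: Within", "group:condition"))
}

#' Correlations between behavioral measures with significance flags
#'
#' Pearson (default) correlations between per-subject measures with pairwise
#' deletion and two-sided significance flags at 0.10 / 0.05 / 0.01 / 0.001
#' (`.`, `*`, `**`, `***`).
#'
#' @param measures numeric data frame or matrix, one row per subject.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` (correlation matrix), `p` (two-sided p values),
#'   `flags` (character matrix) and `n` (pairwise sample sizes).
#' @export
measure_correlations <- function(measures, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as.matrix(measures)
  if (nrow(m) < 3) stop_invalid("need at least three subjects")
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  pv <- r
  nmat <- matrix(0L, p, p, dimnames = dimnames(r))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      nmat[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; pv[i, j] <- 0; next }
      x <- m[ok, i]; y <- m[ok, j]
      if (sum(ok) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = method))
      r[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
  }
  flags <- matrix("", p, p, dimnames = dimnames(r))
  flags[!is.na(pv) & pv < 0.10] <- "."
  flags[!is.na(pv) & pv < 0.05] <- "*"
  flags[!is.na(pv) & pv < 0.01] <- "**"
  flags[!is.na(pv) & pv < 0.001] <- "***"
  diag(flags) <- ""
  list(r = r, p = pv, flags = flags, n = nmat)
}

#' Paired t test with degenerate-input flagging
#'
#' @param values_a,values_b paired numeric vectors of equal length (>= 2).
#' @return list with `t`, `dof`, `p`, `mean_difference`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    stop_invalid("paired vectors must have equal length >= 2")
  }
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, dof = length(d) - 1L, p = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter), p = ht$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}

#' Two-sample t test (pooled by default) with degenerate-input flagging
#'
#' @param values numeric vector.
#' @param labels group labels (exactly two groups, each n >= 2).
#' @param pooled use the pooled-variance Student test with
#'   dof = n1 + n2 - 2 (default `TRUE`); otherwise Welch.
#' @return list with `t`, `dof`, `p`, `group_means`, `degenerate`.
#' @export
two_sample_t <- function(values, labels, pooled = TRUE) {
  gs <- unique(labels)
  if (length(gs) != 2) stop_invalid("need exactly two groups, got %d", length(gs))
  x <- values[labels == gs[1]]; y <- values[labels == gs[2]]
  if (length(x) < 2 || length(y) < 2) stop_invalid("each group needs at least two values")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    return(list(t = NA_real_, dof = length(values) - 2L, p = NA_real_,
                group_means = stats::setNames(c(mean(x), mean(y)), gs),
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), dof = unname(ht$parameter), p = ht$p.value,
       group_means = stats::setNames(c(mean(x), mean(y)), gs),
       degenerate = FALSE)
}
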