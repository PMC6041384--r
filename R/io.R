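# Readers and writers for the package's plain-text formats: BIDS-style
# event TSVs, ROI time-series CSVs, trial CSVs and similarity-matrix CSVs.
# Every reader validates the schema on load and names the offending row in
# its error message.

#' Read an event table from a BIDS-style TSV
#'
#' Expected columns: `onset`, `duration`, `trial_type`, `stimulus_id` and
#' optionally `run`. Onsets must be strictly increasing within each run and
#' durations positive.
#'
#' @param path file path.
#' @return an `event_table`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type", "stimulus_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_invalid("events file %s is missing column(s): %s", path,
                                 paste(miss, collapse = ", "))
  ev <- data.frame(stimulus_id = as.character(df$stimulus_id),
                   condition = as.character(df$trial_type),
                   onset = as.numeric(df$onset),
                   duration = as.numeric(df$duration),
                   run = as.integer(df$run %||% 1L),
                   stringsAsFactors = FALSE)
  bad <- which(ev$duration <= 0)
  if (length(bad)) stop_invalid("non-positive duration at row %d of %s", bad[1], path)
  for (r in unique(ev$run)) {
    on <- ev$onset[ev$run == r]
    if (length(on) > 1 && any(diff(on) <= 0)) {
      row <- which(ev$run == r)[which(diff(on) <= 0)[1] + 1L]
      stop_invalid("onsets not strictly increasing at row %d of %s", row, path)
    }
  }
  class(ev) <- c("event_table", class(ev))
  ev
}

#' Write an event table as a BIDS-style TSV
#'
#' @param events an `event_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$condition,
                    stimulus_id = events$stimulus_id,
                    run = events$run %||% 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ROI time-series matrix from CSV
#'
#' Rows are scans, columns are ROI ids.
#'
#' @param path file path.
#' @return numeric matrix (scans x ROI).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop_invalid("time series file %s must be numeric", path)
  m
}

#' Write an ROI time-series matrix as CSV
#'
#' @param series numeric matrix (scans x ROI).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Expected columns: `subject_id`, `task`, `condition`, `rt`, `correct`.
#'
#' @param path file path.
#' @return a `trial_table`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "task", "condition", "rt", "correct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_invalid("trials file %s is missing column(s): %s", path,
                                 paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$rt) | df$rt <= 0)
  if (length(bad)) stop_invalid("invalid RT at row %d of %s", bad[1], path)
  df$correct <- as.logical(df$correct)
  validate_trials(df)
  class(df) <- c("trial_table", class(df))
  df
}

#' Write a trial table as CSV
#'
#' @param trials a `trial_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from CSV
#'
#' @param path file path (square CSV, first column = word ids).
#' @param kind similarity kind (`brain`, `phonological`, `semantic`).
#' @return a `similarity_matrix`.
#' @export
read_similarity <- function(path, kind = "brain") {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  similarity_matrix(m, ids, kind = kind)
}

#' Write a similarity matrix as CSV
#'
#' @param sim a `similarity_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(word_id = sim$word_ids, sim$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
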