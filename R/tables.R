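#' Event tables and spike tables
#'
#' An event table holds the behavioural ground truth: one row per event (tap
#' or metronome stimulus) with the trial, task condition, target interval and
#' event time. A spike table holds one row per spike with trial, neuron and
#' spike time. Both are plain data frames with a class tag and light
#' validation, written and read as tab-delimited text with a JSON sidecar.
#'
#' @param trial_id integer or character trial identifier (recycled).
#' @param condition task condition label, e.g. "SC", "CC", "ST", "SRTT".
#' @param target_interval_ms instructed interval (ms); NA for reactive trials.
#' @param tap_times_ms,stimulus_times_ms event times (ms) within the trial.
#' @return data.frame of class \code{event_table} with columns
#'   \code{trial_id}, \code{condition}, \code{target_interval_ms},
#'   \code{event}, \code{time_ms}.
#' @export
event_table <- function(trial_id, condition, target_interval_ms,
                        tap_times_ms, stimulus_times_ms = numeric(0)) {
  if (is.unsorted(tap_times_ms, strictly = TRUE))
    stop("tap times must be strictly increasing within a trial")
  df <- rbind(
    data.frame(trial_id = trial_id, condition = condition,
               target_interval_ms = target_interval_ms,
               event = "tap", time_ms = as.numeric(tap_times_ms)),
    if (length(stimulus_times_ms))
      data.frame(trial_id = trial_id, condition = condition,
                 target_interval_ms = target_interval_ms,
                 event = "stimulus", time_ms = as.numeric(stimulus_times_ms))
  )
  class(df) <- c("event_table", "data.frame")
  df
}

#' @rdname event_table
#' @param ... event tables to combine.
#' @export
bind_events <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("event_table", "data.frame")
  df
}

#' Tap or stimulus times of one trial
#' @param events an \code{event_table}.
#' @param trial trial identifier.
#' @param what \code{"tap"} or \code{"stimulus"}.
#' @return sorted numeric vector of times (ms).
#' @export
trial_times <- function(events, trial, what = "tap") {
  sort(events$time_ms[events$trial_id == trial & events$event == what])
}

#' @rdname event_table
#' @param neuron_id neuron identifier (recycled).
#' @param spike_times_ms spike times (ms), sorted non-negative.
#' @export
spike_table <- function(trial_id, neuron_id, spike_times_ms) {
  df <- data.frame(trial_id = trial_id, neuron_id = neuron_id,
                   time_ms = as.numeric(spike_times_ms))
  df <- df[order(df$trial_id, df$neuron_id, df$time_ms), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("spike_table", "data.frame")
  df
}

#' Write / read delimited tables with a JSON sidecar
#'
#' Tables are written as tab-delimited text; a \code{.json} sidecar documents
#' the columns and units so the files are self-describing.
#'
#' @param x an \code{event_table} or \code{spike_table}.
#' @param path output path for the \code{.tsv} file.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(columns = names(x),
               class = class(x)[1],
               units = list(time_ms = "milliseconds"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @param class_tag class to restore ("event_table" or "spike_table").
#' @export
read_table_tsv <- function(path, class_tag = "event_table") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c(class_tag, "data.frame")
  df
}

#' Write a dense rate matrix as a binary array with a JSON sidecar
#'
#' The matrix is stored as little-endian float64 in column-major order; the
#' sidecar names the axes, dimensions and sampling so the array can be
#' re-loaded without guesswork.
#'
#' @param activity a \code{population_activity}.
#' @param path output path for the binary file.
#' @export
write_rate_matrix <- function(activity, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(activity$rate), con, size = 8, endian = "little")
  meta <- list(dtype = "float64", order = "column-major",
               dims = dim(activity$rate),
               axes = c("neuron", "time_ms"),
               time_ms = list(start = activity$time_ms[1], step = 1),
               tap_times_ms = activity$tap_times_ms,
               target_interval_ms = activity$target_interval_ms,
               condition = activity$condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
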