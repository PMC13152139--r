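# Plain-text serialization. Recordings are stored as a directory holding
# meta.json (fs + channel table) and signal.csv (samples x channels); events,
# onsets and ground truth as headed CSV; configs as keyed JSON.

#' Write / read a recording as plain text
#'
#' `write_recording()` creates `dir/meta.json` (sampling rate and channel
#' metadata) and `dir/signal.csv` (one column per channel, one row per
#' sample). `read_recording()` restores the object.
#'
#' @param rec an [ecog_recording()].
#' @param dir target directory (created if missing).
#' @return `write_recording()` the directory invisibly; `read_recording()`
#'   an [ecog_recording()].
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "ecog_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(fs = rec$fs, channels = rec$channels),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  sig <- as.data.frame(t(rec$signal))
  names(sig) <- rec$channels$name
  utils::write.csv(sig, file.path(dir, "signal.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sig <- utils::read.csv(file.path(dir, "signal.csv"), check.names = FALSE)
  ch <- as.data.frame(meta$channels)
  ecog_recording(t(as.matrix(sig)), meta$fs, ch)
}

#' Write / read an event table as CSV
#'
#' Columns: `trial_id`, `finger`, `cue_time_s`, `marker_time_s`, `excluded`.
#'
#' @param events an [event_table()].
#' @param path CSV file path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  event_table(df$trial_id, df$finger, df$cue_time_s, df$marker_time_s, df$excluded)
}

#' Write / read an onset table as CSV
#'
#' @param onsets an `onset_table` from [detect_onsets()].
#' @param path CSV file path.
#' @export
write_onsets <- function(onsets, path) {
  utils::write.csv(as.data.frame(onsets), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_onsets
#' @export
read_onsets <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("onset_table", "data.frame")
  out
}

#' Write / read synthetic ground truth as CSV
#'
#' Two files: `<stem>_trials.csv` (true movement time per trial) and
#' `<stem>_channels.csv` (true onset and region per channel).
#'
#' @param truth a `synth_truth` from [generate_recording()].
#' @param stem path stem without extension.
#' @export
write_ground_truth <- function(truth, stem) {
  utils::write.csv(data.frame(trial = seq_along(truth$true_movement_time_s),
                              true_movement_time_s = truth$true_movement_time_s),
                   paste0(stem, "_trials.csv"), row.names = FALSE)
  utils::write.csv(data.frame(channel = seq_along(truth$true_onset_s),
                              true_onset_s = truth$true_onset_s,
                              region = truth$region_of_channel),
                   paste0(stem, "_channels.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(stem) {
  tr <- utils::read.csv(paste0(stem, "_trials.csv"))
  ch <- utils::read.csv(paste0(stem, "_channels.csv"))
  structure(list(true_movement_time_s = tr$true_movement_time_s,
                 true_onset_s = ch$true_onset_s,
                 region_of_channel = ch$region),
            class = "synth_truth")
}

#' Read a generator configuration from a keyed JSON file
#'
#' Unknown keys are rejected; missing keys take the [synth_config()]
#' defaults.
#'
#' @param path JSON file path.
#' @return a [synth_config()].
#' @export
read_synth_config <- function(path) {
  keys <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synth_config))
  bad <- setdiff(names(keys), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(synth_config, keys)
}

#' Write channel statistics as CSV
#'
#' @param stats a `channel_stats` data.frame from [test_task_response()].
#' @param path CSV file path.
#' @export
write_channel_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}

#' Plain-text report of a region ANOVA
#'
#' Mirrors the field's reporting style: `F(df1, df2)`, p-values and post-hoc
#' contrasts.
#'
#' @param anova a `region_anova` object.
#' @param path output file; `NULL` prints to the console.
#' @export
write_anova_report <- function(anova, path = NULL) {
  txt <- utils::capture.output(print(anova))
  if (is.null(path)) cat(txt, sep = "\n") else writeLines(txt, path)
  invisible(path)
}
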