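#' @title Core containers
#' @description S3 containers shared across the pipeline: continuous
#'   recordings, event tables, epoched trial sets, frequency-band
#'   specifications and band power.
#' @name ecogtiming-classes
NULL

REGION_LEVELS <- c("M1", "S1", "CS", "Other")

#' Construct channel metadata
#'
#' @param name character vector of channel names.
#' @param region region label per channel, one of `"M1"`, `"S1"`, `"CS"`,
#'   `"Other"`.
#' @param in_car logical, include channel in the common-average reference pool.
#' @param hand_region logical, channel lies over the hand representation
#'   (metadata supplied with the recording; no localization is performed here).
#' @param bad logical, channel flagged bad.
#' @return data.frame with one row per channel.
#' @export
channel_table <- function(name, region, in_car = TRUE, hand_region = region %in% c("M1", "S1"),
                          bad = FALSE) {
  name <- as.character(name)
  region <- as.character(region)
  if (!all(region %in% REGION_LEVELS)) {
    stop("region labels must be drawn from {", paste(REGION_LEVELS, collapse = ", "), "}")
  }
  n <- length(name)
  df <- data.frame(
    name = name,
    region = region,
    in_car = rep_len(as.logical(in_car), n),
    hand_region = rep_len(as.logical(hand_region), n),
    bad = rep_len(as.logical(bad), n),
    stringsAsFactors = FALSE
  )
  df
}

#' Construct a continuous multichannel recording
#'
#' @param signal numeric matrix, channels x samples (microvolt-scale a.u.).
#' @param fs sampling rate in Hz.
#' @param channels channel metadata as returned by [channel_table()].
#' @return object of class `ecog_recording`.
#' @export
ecog_recording <- function(signal, fs, channels) {
  signal <- as.matrix(signal)
  stopifnot(is.numeric(signal), length(fs) == 1L, fs > 0)
  if (nrow(channels) != nrow(signal)) {
    stop("channel metadata has ", nrow(channels), " rows but signal has ",
         nrow(signal), " channels")
  }
  structure(list(signal = signal, fs = as.numeric(fs), channels = channels),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$channels$region)),
                                  table(x$channels$region)), collapse = " "),
      "| bad:", sum(x$channels$bad), "\n")
  invisible(x)
}

#' Construct an event table
#'
#' One row per trial: cue time, moved finger, optional movement marker and an
#' exclusion flag.
#'
#' @param trial_id integer trial identifiers.
#' @param finger finger label per trial.
#' @param cue_time_s cue onset in seconds from recording start.
#' @param marker_time_s per-trial movement marker (NA until alignment).
#' @param excluded logical exclusion flag.
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(trial_id, finger, cue_time_s, marker_time_s = NA_real_,
                        excluded = FALSE) {
  n <- length(cue_time_s)
  if (is.unsorted(cue_time_s, strictly = TRUE)) {
    stop("cue times must be strictly increasing")
  }
  df <- data.frame(
    trial_id = rep_len(as.integer(trial_id), n),
    finger = rep_len(as.character(finger), n),
    cue_time_s = as.numeric(cue_time_s),
    marker_time_s = rep_len(as.numeric(marker_time_s), n),
    excluded = rep_len(as.logical(excluded), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("event_table", "data.frame")
  df
}

#' Construct an epoched trial set
#'
#' @param data numeric array, trials x channels x time.
#' @param time_s time axis in seconds relative to the per-trial marker.
#' @param fs sampling rate of the time axis in Hz.
#' @param finger finger label per trial.
#' @param channels channel metadata for the retained channels.
#' @param trial_id original trial identifiers.
#' @return object of class `ecog_trialset`.
#' @export
ecog_trialset <- function(data, time_s, fs, finger, channels, trial_id = seq_len(dim(data)[1])) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(time_s),
            dim(data)[1] == length(finger), dim(data)[2] == nrow(channels))
  structure(list(data = data, time_s = as.numeric(time_s), fs = as.numeric(fs),
                 finger = as.character(finger), channels = channels,
                 trial_id = as.integer(trial_id)),
            class = "ecog_trialset")
}

#' @export
print.ecog_trialset <- function(x, ...) {
  cat(sprintf("<ecog_trialset> %d trials x %d channels x %d samples, t in [%.3g, %.3g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Frequency-band specification
#'
#' Band direction encodes the expected movement-related change: the
#' high-frequency band (HFB) increases in power, while alpha, beta and the
#' combined low-frequency band (LFB) desynchronize (decrease).
#'
#' @param name one of `"alpha"`, `"beta"`, `"lfb"`, `"hfb"`.
#' @param low,high band edges in Hz (1 Hz bins, endpoints inclusive).
#' @param direction `"increase"` or `"decrease"`; defaults to the canonical
#'   direction for `name`.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(name, low, high, direction = NULL) {
  name <- match.arg(tolower(name), c("alpha", "beta", "lfb", "hfb"))
  if (is.null(direction)) direction <- if (name == "hfb") "increase" else "decrease"
  direction <- match.arg(direction, c("increase", "decrease"))
  if (name == "hfb" && direction != "increase") stop("HFB direction must be 'increase'")
  if (name != "hfb" && direction != "decrease") {
    stop("alpha/beta/LFB direction must be 'decrease'")
  }
  stopifnot(low < high, low > 0)
  structure(list(name = name, low = low, high = high, direction = direction),
            class = "band_spec")
}

#' Canonical frequency bands
#'
#' Default definitions: alpha 8-12 Hz, beta 13-30 Hz, LFB 8-30 Hz,
#' HFB 60-100 Hz. Per-participant overrides (e.g. an HFB of 30-100 Hz and a
#' beta of 13-20 Hz for a participant whose responses sit lower) are supplied
#' as a named list of `c(low, high)` pairs.
#'
#' @param overrides named list, e.g. `list(hfb = c(30, 100))`.
#' @return named list of [band_spec()] objects.
#' @export
default_bands <- function(overrides = NULL) {
  defs <- list(alpha = c(8, 12), beta = c(13, 30), lfb = c(8, 30), hfb = c(60, 100))
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      nm2 <- tolower(nm)
      if (!nm2 %in% names(defs)) stop("unknown band override: ", nm)
      defs[[nm2]] <- overrides[[nm]]
    }
  }
  lapply(names(defs), function(nm) band_spec(nm, defs[[nm]][1], defs[[nm]][2])) |>
    stats::setNames(names(defs))
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz (%s)\n", x$name, x$low, x$high, x$direction))
  invisible(x)
}

#' Band power container
#'
#' A trial set whose data hold band-averaged spectral power. Samples
#' invalidated by wavelet edge effects are `NA`.
#'
#' @param data trials x channels x time array of non-negative power (a.u.).
#' @param time_s,fs,finger,channels,trial_id as in [ecog_trialset()].
#' @param band a [band_spec()].
#' @return object of class `band_power` (inherits `ecog_trialset`).
#' @export
band_power <- function(data, time_s, fs, finger, channels, band,
                       trial_id = seq_len(dim(data)[1])) {
  if (any(data < 0, na.rm = TRUE)) stop("band power must be non-negative")
  ts <- ecog_trialset(data, time_s, fs, finger, channels, trial_id)
  ts$band <- band
  class(ts) <- c("band_power", class(ts))
  ts
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> band %s (%g-%g Hz, %s): ", x$band$name, x$band$low,
              x$band$high, x$band$direction))
  NextMethod()
}

# internal: index range of a time interval [lo, hi] on a time axis
.time_window_idx <- function(time_s, window) {
  idx <- which(time_s >= window[1] - 1e-9 & time_s <= window[2] + 1e-9)
  if (length(idx) == 0L) {
    stop(sprintf("interval [%g, %g] s lies outside the epoch [%g, %g] s",
                 window[1], window[2], min(time_s), max(time_s)))
  }
  idx
}

# internal: per-trial mean of one channel over a set of time indices
.trial_window_means <- function(ts, ch, idx) {
  rowMeans(matrix(ts$data[, ch, idx], dim(ts$data)[1], length(idx)), na.rm = TRUE)
}

# internal: subset trials of a trial set / band power
.subset_trials <- function(ts, keep) {
  ts$data <- ts$data[keep, , , drop = FALSE]
  ts$finger <- ts$finger[keep]
  ts$trial_id <- ts$trial_id[keep]
  ts
}

# internal: subset channels
.subset_channels <- function(ts, keep) {
  ts$data <- ts$data[, keep, , drop = FALSE]
  ts$channels <- ts$channels[keep, , drop = FALSE]
  ts
}
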