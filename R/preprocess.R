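#' Flag bad channels by robust variance screening
#'
#' Channels with near-zero variance (broken leads, flat signals) or grossly
#' inflated variance (noisy leads) are flagged and excluded from all later
#' stages including the common-average reference. Thresholds are relative to
#' the median channel variance, so the rule is scale-free. A manual override
#' list is honored in addition to the automatic rule.
#'
#' @param rec an [ecog_recording()].
#' @param variance_low,variance_high multiples of the median channel variance
#'   below/above which a channel is flagged (defaults 1e-3 and 25).
#' @param manual_bad channel names or indices to flag regardless.
#' @return the recording with updated `channels$bad` flags.
#' @export
detect_bad_channels <- function(rec, variance_low = 1e-3, variance_high = 25,
                                manual_bad = NULL) {
  stopifnot(inherits(rec, "ecog_recording"), nrow(rec$signal) >= 2)
  v <- apply(rec$signal, 1, stats::var)
  med <- stats::median(v)
  # exactly-zero variance is always flat/broken, even if the median is 0 too
  bad <- v == 0 | (med > 0 & (v < variance_low * med | v > variance_high * med))
  if (!is.null(manual_bad)) {
    idx <- if (is.character(manual_bad)) match(manual_bad, rec$channels$name) else manual_bad
    bad[idx] <- TRUE
  }
  if (all(bad)) stop("all channels flagged bad; check the recording and thresholds")
  rec$channels$bad <- rec$channels$bad | bad
  rec
}

#' Common-average reference
#'
#' Subtracts, from every retained channel, the per-sample mean of all
#' non-bad channels whose `in_car` flag is set. The CAR pool may include
#' channels that are excluded from analysis (e.g. clinical channels recorded
#' on the same amplifier).
#'
#' @param rec an [ecog_recording()].
#' @return re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "ecog_recording"))
  pool <- rec$channels$in_car & !rec$channels$bad
  if (sum(pool) < 2) stop("need at least 2 non-bad in_CAR channels for CAR")
  car <- colMeans(rec$signal[pool, , drop = FALSE])
  rec$signal <- sweep(rec$signal, 2, car)
  rec
}

#' Amplifier-equalizing band-pass and line-noise notch
#'
#' Zero-phase band-pass (default 0.15-134 Hz, realized as a cascaded
#' 2nd-order Butterworth high-pass and 4th-order Butterworth low-pass) plus a
#' 2nd-order notch (default 50 Hz, Q = 35), applied forward-backward so that
#' no phase delay can bias onset latencies.
#'
#' @param rec an [ecog_recording()].
#' @param band band-pass edges in Hz.
#' @param notch_hz notch center frequency (set `NULL` to skip).
#' @param notch_q notch quality factor.
#' @return filtered recording.
#' @export
equalize_filter <- function(rec, band = c(0.15, 134), notch_hz = 50, notch_q = 35) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (rec$fs / 2 <= band[2]) {
    stop(sprintf("sampling rate %g Hz too low: band edge %g Hz must lie below the Nyquist frequency %g Hz",
                 rec$fs, band[2], rec$fs / 2))
  }
  X <- t(rec$signal)                       # time x channels
  npad <- round(3 * rec$fs)                # ~3 s edge padding for the 0.15 Hz corner
  hp <- .butter(2, band[1], rec$fs, "high")
  lp <- .butter(4, band[2], rec$fs, "low")
  X <- .filtfilt_mat(hp$b, hp$a, X, npad)
  X <- .filtfilt_mat(lp$b, lp$a, X, npad)
  if (!is.null(notch_hz)) {
    nt <- .notch_biquad(notch_hz, rec$fs, notch_q)
    X <- .filtfilt_mat(nt$b, nt$a, X, npad)
  }
  rec$signal <- t(X)
  rec
}

#' Epoch a recording around per-trial markers
#'
#' Cuts one trial per non-excluded event, sample-aligned so that time 0
#' corresponds to the marker. The epoch window is closed `[window[1],
#' window[2]]`: sample indices run from `round(window[1] * fs)` to
#' `round(window[2] * fs)` relative to the marker sample, so a (-1, 2) s
#' window at fs 512 yields `round(3 * 512) + 1` samples. Trials whose
#' window falls partly outside the recording are dropped with a warning.
#' Bad channels are removed from the trial set.
#'
#' @param rec an [ecog_recording()].
#' @param events an [event_table()] whose non-excluded rows carry
#'   `marker_time_s`.
#' @param window epoch window in seconds relative to the marker.
#' @param align take `"marker"` (default) or `"cue"` times as time zero.
#' @return an [ecog_trialset()].
#' @export
epoch_trials <- function(rec, events, window = c(-1, 2), align = c("marker", "cue")) {
  stopifnot(inherits(rec, "ecog_recording"))
  align <- match.arg(align)
  ev <- events[!events$excluded, , drop = FALSE]
  anchor <- if (align == "marker") ev$marker_time_s else ev$cue_time_s
  if (anyNA(anchor)) {
    stop("event(s) without a marker time: trial(s) ",
         paste(ev$trial_id[is.na(anchor)], collapse = ", "))
  }
  fs <- rec$fs
  rel <- seq.int(round(window[1] * fs), round(window[2] * fs))
  n <- ncol(rec$signal)
  keep_ch <- which(!rec$channels$bad)
  start <- round(anchor * fs)
  inside <- start + rel[1] >= 1 & start + rel[length(rel)] <= n
  if (any(!inside)) {
    warning(sum(!inside), " trial(s) dropped: epoch window extends past the recording edge")
  }
  ev <- ev[inside, , drop = FALSE]
  start <- start[inside]
  dat <- array(NA_real_, c(nrow(ev), length(keep_ch), length(rel)))
  for (i in seq_len(nrow(ev))) {
    dat[i, , ] <- rec$signal[keep_ch, start[i] + rel, drop = FALSE]
  }
  ecog_trialset(dat, rel / fs, fs, ev$finger,
                rec$channels[keep_ch, , drop = FALSE], ev$trial_id)
}

#' Reject trials by manual list and amplitude criterion
#'
#' Removes trials named in `manual_exclusions` and, in addition, trials whose
#' peak absolute z-scored amplitude on any channel exceeds
#' `amplitude_z_limit` (z-scoring is per channel across all trials and time
#' points). This automates the visual artifact screening step.
#'
#' @param ts an [ecog_trialset()].
#' @param manual_exclusions trial ids to drop.
#' @param amplitude_z_limit rejection threshold in robust z-units.
#' @return trial set without the rejected trials.
#' @export
reject_trials <- function(ts, manual_exclusions = integer(0), amplitude_z_limit = 10) {
  stopifnot(inherits(ts, "ecog_trialset"))
  drop_manual <- ts$trial_id %in% manual_exclusions
  nt <- dim(ts$data)[1]; nc <- dim(ts$data)[2]
  peak_z <- rep(FALSE, nt)
  for (ch in seq_len(nc)) {
    x <- ts$data[, ch, , drop = TRUE]
    mu <- mean(x, na.rm = TRUE); sdv <- stats::sd(as.vector(x), na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) next
    peak_z <- peak_z | apply(abs(x - mu) / sdv, 1, max, na.rm = TRUE) > amplitude_z_limit
  }
  drop <- drop_manual | peak_z
  if (all(drop)) stop("all trials rejected; check exclusion list and z limit")
  if (any(drop)) {
    message(sprintf("reject_trials: dropped %d trial(s) (%d manual, %d amplitude)",
                    sum(drop), sum(drop_manual), sum(peak_z & !drop_manual)))
  }
  .subset_trials(ts, !drop)
}
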