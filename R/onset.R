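#' Threshold search parameters
#'
#' @param start starting threshold magnitude in z-units (the sign follows the
#'   band direction: +0.4 for power increases, -0.4 for decreases).
#' @param step grid step in z-units (> 0).
#' @param window time window (s) in which "reaching the threshold" is
#'   evaluated during optimization.
#' @param spare_channels number of channels allowed to remain above/below the
#'   threshold at the window start during phase 1 ("all but two").
#' @return object of class `threshold_search`.
#' @export
threshold_search <- function(start = 0.4, step = 0.1, window = c(-0.5, 0.5),
                             spare_channels = 2) {
  stopifnot(start > 0, step > 0, window[1] < window[2], spare_channels >= 0)
  structure(list(start = start, step = step, window = window,
                 spare_channels = spare_channels), class = "threshold_search")
}

#' Smooth band-power trials with a centered moving average
#'
#' Centered moving average of each trial's time course with a `window_s`
#' window; windows shrink at the epoch edges and `NA` (wavelet-invalidated)
#' samples are excluded from the local mean.
#'
#' @param bp a [band_power()] (or any [ecog_trialset()]).
#' @param window_s smoothing window length in seconds.
#' @return the object with smoothed data.
#' @export
smooth_trials <- function(bp, window_s = 0.5) {
  stopifnot(inherits(bp, "ecog_trialset"))
  d <- dim(bp$data)
  if (window_s >= diff(range(bp$time_s))) stop("smoothing window must be shorter than the epoch")
  w <- max(1L, round(window_s * bp$fs))
  if (w %% 2L == 0L) w <- w + 1L         # symmetric window
  X <- t(matrix(bp$data, d[1] * d[2], d[3]))   # time x (trial*channel)
  S <- .runmean_na(X, w)
  bp$data <- aperm(array(S, c(d[3], d[1], d[2])), c(2, 3, 1))
  bp
}

# centered moving average of each column, NA-aware, shrinking at the edges
.runmean_na <- function(X, w) {
  n <- nrow(X)
  h <- (w - 1L) %/% 2L
  valid <- !is.na(X)
  Xz <- X
  Xz[!valid] <- 0
  cs <- rbind(0, apply(Xz, 2, cumsum))
  cn <- rbind(0, apply(valid + 0, 2, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sums <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  cnts <- cn[hi + 1L, , drop = FALSE] - cn[lo, , drop = FALSE]
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Normalized per-channel mean traces
#'
#' Computes the mean over (smoothed) trials per channel, z-scores it over the
#' full epoch (mean 0, SD 1) and subtracts the mean of the pre-movement
#' baseline interval, so the baseline mean is exactly zero per channel.
#' Channels with zero variance are dropped with a warning.
#'
#' @param bp a smoothed [band_power()].
#' @param baseline baseline interval in seconds (default `c(-1, -0.5)`).
#' @return object of class `onset_traces`: list with `traces` (channels x
#'   time), `time_s`, `fs`, `band`, `channels`, `finger` (label of the trial
#'   subset, `NA` if mixed) and `baseline`.
#' @export
normalize_channels <- function(bp, baseline = c(-1, -0.5)) {
  stopifnot(inherits(bp, "band_power"))
  d <- dim(bp$data)
  if (d[1] < 1) stop("need at least one trial")
  m <- apply(bp$data, c(2, 3), mean)        # channels x time (NA edges stay NA)
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " channel(s) with zero-variance mean trace: ",
            paste(bp$channels$name[bad], collapse = ", "))
    if (all(bad)) stop("no channel with finite variance")
  }
  z <- (m - mu) / sdv
  bidx <- .time_window_idx(bp$time_s, baseline)
  z <- z - rowMeans(z[, bidx, drop = FALSE], na.rm = TRUE)
  keep <- which(!bad)
  fingers <- unique(bp$finger)
  structure(list(traces = z[keep, , drop = FALSE], time_s = bp$time_s, fs = bp$fs,
                 band = bp$band, channels = bp$channels[keep, , drop = FALSE],
                 finger = if (length(fingers) == 1L) fingers else NA_character_,
                 baseline = baseline),
            class = "onset_traces")
}

#' Construct a normalized trace set directly
#'
#' Mostly used internally (by [normalize_channels()]) and in tests; allows
#' externally computed normalized traces to enter the onset stage.
#'
#' @param traces channels x time matrix of normalized band power (z-units).
#' @param time_s time axis in seconds.
#' @param band a [band_spec()].
#' @param channels channel metadata ([channel_table()]).
#' @param finger finger label.
#' @param fs sampling rate of the time axis; inferred from `time_s` if NULL.
#' @param baseline baseline interval used for the correction.
#' @return object of class `onset_traces`.
#' @export
onset_traces <- function(traces, time_s, band, channels, finger = NA_character_,
                         fs = NULL, baseline = c(-1, -0.5)) {
  traces <- as.matrix(traces)
  stopifnot(ncol(traces) == length(time_s), nrow(traces) == nrow(channels),
            inherits(band, "band_spec"))
  if (is.null(fs)) fs <- 1 / stats::median(diff(time_s))
  structure(list(traces = traces, time_s = as.numeric(time_s), fs = fs,
                 band = band, channels = channels, finger = finger,
                 baseline = baseline),
            class = "onset_traces")
}

#' @export
print.onset_traces <- function(x, ...) {
  cat(sprintf("<onset_traces> %d channels, band %s, finger %s\n",
              nrow(x$traces), x$band$name, x$finger))
  invisible(x)
}

# linear interpolation of a trace at an arbitrary time point
.trace_at <- function(trace, time_s, t0) {
  if (t0 <= time_s[1]) return(trace[1])
  if (t0 >= time_s[length(time_s)]) return(trace[length(trace)])
  stats::approx(time_s, trace, xout = t0, rule = 2)$y
}

#' Optimize the onset-detection threshold
#'
#' Two-phase grid search over threshold magnitudes `start, start + step, ...`
#' applied in the band's direction (positive for power increases, negative
#' for decreases). Phase 1 grows the magnitude until the threshold exceeds
#' the trace value at the window start (t = `search$window[1]`, i.e. -0.5 s)
#' of all but `spare_channels` channels, anchoring it above the pre-movement
#' level. Phase 2 keeps growing while the number of channels that reach the
#' threshold anywhere inside the window does not decrease; the value returned
#' is the last one before the count drops (for a plateau followed by a drop,
#' the last plateau value). This yields the strongest response level still
#' reached by the majority of channels, so relative differences between
#' channels are preserved.
#'
#' With fewer than 3 channels, phase 1's "all but two" is vacuous and the
#' fixed starting magnitude is returned with a warning.
#'
#' @param traces an `onset_traces` object.
#' @param search a [threshold_search()].
#' @param phase2 set `FALSE` for the permissive variant that stops after
#'   phase 1.
#' @return signed threshold in z-units (negative for decrease bands), with
#'   attribute `"n_reaching"` (channels reaching it inside the window).
#' @export
optimize_threshold <- function(traces, search = threshold_search(), phase2 = TRUE) {
  stopifnot(inherits(traces, "onset_traces"))
  dir <- if (traces$band$direction == "increase") 1 else -1
  D <- dir * traces$traces                 # work in "increase" orientation
  nch <- nrow(D)
  sgn_th <- function(th) dir * th
  if (nch < 3L) {
    warning("fewer than 3 channels: phase 1 is vacuous, using the fixed starting threshold")
    return(structure(sgn_th(search$start),
                     n_reaching = .n_reaching(D, traces$time_s, search$window, search$start)))
  }
  v_start <- apply(D, 1, .trace_at, time_s = traces$time_s, t0 = search$window[1])
  if (.n_reaching(D, traces$time_s, search$window, search$start) == 0L) {
    stop("no channel reaches the starting threshold |", search$start,
         "| inside the window; skip this band/finger")
  }
  th <- search$start
  # phase 1: climb above the window-start level of all but `spare` channels
  while (sum(v_start >= th) > search$spare_channels) th <- th + search$step
  if (!phase2) {
    return(structure(sgn_th(th),
                     n_reaching = .n_reaching(D, traces$time_s, search$window, th)))
  }
  # phase 2: climb while the count of channels reaching the threshold holds
  n_cur <- .n_reaching(D, traces$time_s, search$window, th)
  if (n_cur == 0L) {
    warning("no channel reaches the phase-1 threshold inside the window; returning it unchanged")
    return(structure(sgn_th(th), n_reaching = 0L))
  }
  repeat {
    th2 <- th + search$step
    n2 <- .n_reaching(D, traces$time_s, search$window, th2)
    if (n2 < n_cur) {
      if (n2 == 0L && n_cur == nch) {
        warning("channel count never dropped below the full set before the traces' maxima; returning the largest reached threshold")
      }
      break
    }
    th <- th2
    n_cur <- n2
  }
  structure(sgn_th(th), n_reaching = n_cur)
}

# number of channels with at least one sample >= th inside the window
# (D is oriented so that responses are increases)
.n_reaching <- function(D, time_s, window, th) {
  idx <- .time_window_idx(time_s, window)
  sum(apply(D[, idx, drop = FALSE] >= th, 1, any, na.rm = TRUE))
}

#' Detect per-channel neural onsets
#'
#' The neural onset of a channel is the first time in the epoch at which its
#' normalized mean trace crosses the threshold in the band's direction
#' (increase above a positive threshold, decrease below a negative one).
#' Crossing times are linearly interpolated between samples. Channels that
#' never cross are omitted with a message; channels already beyond the
#' threshold at the first valid sample are reported at that sample and
#' flagged in the `crossed_at_start` column.
#'
#' @param traces an `onset_traces` object.
#' @param threshold signed threshold in z-units, typically from
#'   [optimize_threshold()].
#' @return data.frame of class `onset_table` with columns `channel`,
#'   `finger`, `band`, `onset_s`, `threshold_used`, `region`,
#'   `crossed_at_start`.
#' @export
detect_onsets <- function(traces, threshold) {
  stopifnot(inherits(traces, "onset_traces"))
  dir <- if (traces$band$direction == "increase") 1 else -1
  if (sign(threshold) != dir) {
    stop("threshold sign does not match the band direction")
  }
  D <- dir * traces$traces
  thm <- abs(threshold)
  tt <- traces$time_s
  res <- lapply(seq_len(nrow(D)), function(ch) {
    y <- D[ch, ]
    ok <- which(!is.na(y))
    yv <- y[ok]
    above <- yv >= thm
    if (!any(above)) return(NULL)
    first <- which(above)[1]
    if (first == 1L) {
      return(data.frame(onset_s = tt[ok[1]], crossed_at_start = TRUE, idx = ch))
    }
    i0 <- ok[first - 1L]; i1 <- ok[first]
    frac <- (thm - yv[first - 1L]) / (yv[first] - yv[first - 1L])
    data.frame(onset_s = tt[i0] + frac * (tt[i1] - tt[i0]),
               crossed_at_start = FALSE, idx = ch)
  })
  missed <- vapply(res, is.null, logical(1))
  if (any(missed)) {
    message("detect_onsets: ", sum(missed), " channel(s) never cross the threshold: ",
            paste(traces$channels$name[missed], collapse = ", "))
  }
  res <- do.call(rbind, res)
  out <- data.frame(
    channel = character(0), finger = character(0), band = character(0),
    onset_s = numeric(0), threshold_used = numeric(0), region = character(0),
    crossed_at_start = logical(0), stringsAsFactors = FALSE
  )
  if (!is.null(res)) {
    out <- data.frame(
      channel = traces$channels$name[res$idx],
      finger = traces$finger,
      band = traces$band$name,
      onset_s = res$onset_s,
      threshold_used = as.numeric(threshold),
      region = traces$channels$region[res$idx],
      crossed_at_start = res$crossed_at_start,
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("onset_table", "data.frame")
  out
}

#' Permissive-variant onset detection
#'
#' Identical to [optimize_threshold()] + [detect_onsets()] but the threshold
#' search stops after phase 1 (the "keep growing until the channel count
#' drops" rule is disabled). Permissive thresholds are therefore never larger
#' in magnitude than the full rule's, and each channel's permissive onset is
#' at or before its full-rule onset.
#'
#' @inheritParams optimize_threshold
#' @return an `onset_table` (see [detect_onsets()]).
#' @export
detect_onsets_permissive <- function(traces, search = threshold_search()) {
  th <- optimize_threshold(traces, search, phase2 = FALSE)
  detect_onsets(traces, as.numeric(th))
}
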