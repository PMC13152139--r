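#' GSM (gamma-slope marker) configuration
#'
#' @param band HFB band edges in Hz used for the alignment trace.
#' @param pre_interval_s,post_interval_s intervals (s, cue-relative) whose
#'   mean power is compared when selecting responsive channels; the pre
#'   interval must end at or before 0 and the post interval start at or
#'   after 0.
#' @param slope slope of the sliding line segment in z-units per second.
#' @param segment_len_s length of the segment in seconds.
#' @param search_window_s window (s, cue-relative) searched for the marker.
#' @param smooth_s smoothing applied to the mean trace before matching (same
#'   0.5 s as onset detection; assumption, configurable).
#' @return object of class `gsm_config`.
#' @export
gsm_config <- function(band = c(60, 100), pre_interval_s = c(-0.5, 0),
                       post_interval_s = c(0.5, 1), slope = 2,
                       segment_len_s = 0.4, search_window_s = c(0, 2),
                       smooth_s = 0.5) {
  if (pre_interval_s[2] > 0) stop("pre interval must end at or before the cue")
  if (post_interval_s[1] < 0) stop("post interval must start at or after the cue")
  stopifnot(slope > 0, segment_len_s > 0)
  structure(list(band = band, pre_interval_s = pre_interval_s,
                 post_interval_s = post_interval_s, slope = slope,
                 segment_len_s = segment_len_s, search_window_s = search_window_s,
                 smooth_s = smooth_s),
            class = "gsm_config")
}

#' Movement-onset markers from dataglove traces
#'
#' Convolves the moved finger's glove trace with a derivative-of-Gaussian
#' kernel (scale `sigma_s`) and takes, per trial, the first time after the
#' cue at which the convolved signal exceeds `deflect_z` baseline standard
#' deviations (baseline: the second before the cue). Trials with no crossing
#' before the next cue are flagged excluded (mirroring visual rejection);
#' per-trial manual overrides replace the semi-automated visual correction.
#'
#' @param glove a `glove_trace`.
#' @param events an [event_table()].
#' @param sigma_s Gaussian scale in seconds (default 0.05).
#' @param deflect_z detection threshold in baseline SDs (default 3).
#' @param overrides named numeric vector of marker times (s), names = trial ids.
#' @return the event table with `marker_time_s` filled in and non-detected
#'   trials flagged `excluded`.
#' @export
detect_mom <- function(glove, events, sigma_s = 0.05, deflect_z = 3, overrides = NULL) {
  stopifnot(inherits(glove, "glove_trace"))
  fs <- glove$fs
  half <- round(3 * sigma_s * fs)
  tk <- seq.int(-half, half) / fs
  dog <- -tk / sigma_s^2 * exp(-tk^2 / (2 * sigma_s^2))
  dog <- dog / sum(tk * dog)               # unit response to unit positive slope
  n <- nrow(glove$traces)
  # centered correlation with the DoG kernel = smoothed derivative estimate
  conv <- .fir_centered_cpp(glove$traces, dog)
  ev <- events
  bounds <- c(ev$cue_time_s[-1], n / fs)
  for (i in seq_len(nrow(ev))) {
    if (!is.null(overrides) && as.character(ev$trial_id[i]) %in% names(overrides)) {
      ev$marker_time_s[i] <- overrides[[as.character(ev$trial_id[i])]]
      next
    }
    f <- match(ev$finger[i], glove$fingers)
    if (is.na(f)) stop("no glove trace for finger ", ev$finger[i])
    cue_i <- round(ev$cue_time_s[i] * fs)
    base <- conv[max(1, cue_i - round(fs)):cue_i, f]
    sdv <- stats::sd(base, na.rm = TRUE)
    search <- seq.int(cue_i + 1L, min(n, round(bounds[i] * fs)))
    # floor the threshold at a quarter of the trial's peak derivative so that
    # near-noiseless traces are not triggered by the far tail of the kernel
    thr <- max(deflect_z * sdv, 0.25 * max(conv[search, f]))
    hit <- if (thr <= 0) NA_integer_ else search[which(conv[search, f] > thr)[1]]
    if (is.na(hit)) {
      ev$excluded[i] <- TRUE
      message("detect_mom: no deflection found for trial ", ev$trial_id[i], "; excluded")
    } else {
      ev$marker_time_s[i] <- hit / fs
    }
  }
  ev
}

#' Select task-responsive channels for GSM alignment
#'
#' Channels whose mean post-cue HFB power exceeds the pre-cue power at
#' p < 0.05 in an independent two-sample t-test across trials.
#'
#' @param cue_ts a [band_power()] of HFB power epoched around the cue.
#' @param cfg a [gsm_config()].
#' @param alpha significance level.
#' @return character vector of selected channel names (errors if empty: GSM
#'   cannot proceed without a responsive channel pool).
#' @export
select_responsive_channels_for_gsm <- function(cue_ts, cfg = gsm_config(), alpha = 0.05) {
  stopifnot(inherits(cue_ts, "band_power"))
  pre_idx <- .time_window_idx(cue_ts$time_s, cfg$pre_interval_s)
  post_idx <- .time_window_idx(cue_ts$time_s, cfg$post_interval_s)
  d <- dim(cue_ts$data)
  if (d[1] < 2) stop("need at least 2 trials")
  p <- vapply(seq_len(d[2]), function(ch) {
    pre_m <- .trial_window_means(cue_ts, ch, pre_idx)
    post_m <- .trial_window_means(cue_ts, ch, post_idx)
    stats::t.test(post_m, pre_m, var.equal = TRUE, alternative = "greater")$p.value
  }, numeric(1))
  sel <- cue_ts$channels$name[p < alpha]
  if (length(sel) == 0L) {
    stop("GSM aborted: no channel shows a significant HFB response to the cue")
  }
  sel
}

# The one isolated reading of "minimal horizontal distance between the mean
# HFB trace and a sliding slope line segment": the placement minimizing the
# time difference between the segment midpoint and the trace's crossing of
# the segment's mid-level reduces to the trace's first upward crossing of
# level slope * segment_len / 2 (in z-units) inside the search window.
# Substituting a different metric only requires replacing this function.
.gsm_marker_one_trial <- function(trace, time_s, cfg) {
  level <- cfg$slope * cfg$segment_len_s / 2
  idx <- which(time_s >= cfg$search_window_s[1] & time_s <= cfg$search_window_s[2])
  y <- trace[idx]
  ok <- which(!is.na(y))
  if (length(ok) < 2L) return(NA_real_)
  yv <- y[ok]
  above <- yv >= level
  if (!any(above)) return(NA_real_)        # did not converge
  first <- which(above)[1]
  if (first == 1L) return(time_s[idx[ok[1]]])
  t0 <- time_s[idx[ok[first - 1L]]]; t1 <- time_s[idx[ok[first]]]
  frac <- (level - yv[first - 1L]) / (yv[first] - yv[first - 1L])
  t0 + frac * (t1 - t0)
}

#' Gamma-slope markers for trial alignment
#'
#' Per trial, the mean HFB power trace over the selected channels is
#' smoothed, z-scored over the cue epoch and baseline-corrected with the
#' pre-cue interval; the marker is where a sliding line segment of slope
#' `cfg$slope` and length `cfg$segment_len_s` attains minimal horizontal
#' distance to the trace (see the package vignette for the exact reading).
#' Because every channel of a trial is shifted by the same per-trial amount,
#' relative timing across channels is preserved. Trials with no marker inside
#' the search window are flagged excluded ("did not converge").
#'
#' @param cue_ts a [band_power()] of HFB power epoched around the cue
#'   (cue-relative time axis).
#' @param channels channel names from [select_responsive_channels_for_gsm()].
#' @param events the [event_table()] the epochs were cut from.
#' @param cfg a [gsm_config()].
#' @return the event table with `marker_time_s` filled (absolute seconds) and
#'   non-converged trials excluded; errors if more than half the trials fail.
#' @export
detect_gsm <- function(cue_ts, channels, events, cfg = gsm_config()) {
  stopifnot(inherits(cue_ts, "band_power"))
  chi <- match(channels, cue_ts$channels$name)
  if (anyNA(chi)) stop("unknown channel(s): ", paste(channels[is.na(chi)], collapse = ", "))
  sm <- smooth_trials(.subset_channels(cue_ts, chi), cfg$smooth_s)
  ev <- events
  n_fail <- 0L
  pre_idx <- .time_window_idx(sm$time_s, cfg$pre_interval_s)
  for (i in seq_len(dim(sm$data)[1])) {
    slice <- array(sm$data[i, , , drop = FALSE], dim(sm$data)[2:3])
    trace <- colMeans(slice, na.rm = TRUE)
    if (all(is.na(trace)) || stats::sd(trace, na.rm = TRUE) == 0) {
      marker <- NA_real_
    } else {
      z <- (trace - mean(trace, na.rm = TRUE)) / stats::sd(trace, na.rm = TRUE)
      z <- z - mean(z[pre_idx], na.rm = TRUE)
      marker <- .gsm_marker_one_trial(z, sm$time_s, cfg)
    }
    row <- match(sm$trial_id[i], ev$trial_id)
    if (is.na(marker)) {
      ev$excluded[row] <- TRUE
      n_fail <- n_fail + 1L
    } else {
      ev$marker_time_s[row] <- ev$cue_time_s[row] + marker
    }
  }
  if (n_fail > dim(sm$data)[1] / 2) {
    stop("GSM did not converge on more than half of the trials (", n_fail, ")")
  }
  if (n_fail > 0L) message("detect_gsm: ", n_fail, " trial(s) did not converge; excluded")
  ev
}
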