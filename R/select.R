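#' Test channels for a significant task response
#'
#' Per channel, per-trial mean power in a pre-marker and a post-marker
#' interval are compared with a one-sided paired t-test in the band's
#' expected direction (increase for HFB, decrease for alpha/beta/LFB), with
#' no multiple-comparison correction.
#'
#' @param bp a [band_power()].
#' @param pre pre-marker interval in seconds (default `c(-1, -0.5)`).
#' @param post post-marker interval in seconds (default `c(0, 0.5)`).
#' @param alpha significance level (default 0.05).
#' @return data.frame of class `channel_stats`: one row per channel with
#'   `channel`, `band`, `t_statistic`, `p_value`, `significant`, `signed_r2`
#'   (`NA` until [signed_r2()] is merged in), `region`, `in_hand_region` and
#'   `provenance` (`"tested"`; the GSM stage marks inherited significance).
#' @export
test_task_response <- function(bp, pre = c(-1, -0.5), post = c(0, 0.5), alpha = 0.05) {
  stopifnot(inherits(bp, "band_power"))
  d <- dim(bp$data)
  if (d[1] < 2) stop("need at least 2 trials for the paired test")
  pre_idx <- .time_window_idx(bp$time_s, pre)
  post_idx <- .time_window_idx(bp$time_s, post)
  alt <- if (bp$band$direction == "increase") "greater" else "less"
  res <- lapply(seq_len(d[2]), function(ch) {
    pre_m <- .trial_window_means(bp, ch, pre_idx)
    post_m <- .trial_window_means(bp, ch, post_idx)
    tst <- stats::t.test(post_m, pre_m, paired = TRUE, alternative = alt)
    data.frame(t_statistic = unname(tst$statistic), p_value = tst$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    channel = bp$channels$name,
    band = bp$band$name,
    t_statistic = res$t_statistic,
    p_value = res$p_value,
    significant = res$p_value < alpha,
    signed_r2 = NA_real_,
    region = bp$channels$region,
    in_hand_region = bp$channels$hand_region,
    provenance = "tested",
    stringsAsFactors = FALSE
  )
  class(out) <- c("channel_stats", "data.frame")
  out
}

#' Signed coefficient of determination between power and task design
#'
#' Squared Pearson correlation between the per-time-sample band power
#' (concatenated across trials) and an active/rest step-function design,
#' carrying the sign of the correlation. Used to map the spatial extent of
#' the task response.
#'
#' @param bp a [band_power()].
#' @param design either a 0/1 (rest/active) vector on the trial time axis, or
#'   `NULL` to build a step function that is active in `active_window`.
#' @param active_window used when `design` is `NULL` (default `c(0, 1)` s,
#'   movement period).
#' @return named numeric vector of per-channel signed-r2 values in [-1, 1].
#' @export
signed_r2 <- function(bp, design = NULL, active_window = c(0, 1)) {
  stopifnot(inherits(bp, "band_power"))
  nt <- length(bp$time_s)
  if (is.null(design)) {
    design <- as.numeric(bp$time_s >= active_window[1] & bp$time_s <= active_window[2])
  }
  if (length(design) != nt) stop("design must be defined on the trial time axis")
  d <- dim(bp$data)
  dd <- rep(design, each = d[1])           # per trial x time, trial-major
  vapply(seq_len(d[2]), function(ch) {
    x <- as.vector(bp$data[, ch, , drop = TRUE])
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0 || stats::sd(dd[ok]) == 0) {
      warning("zero-variance power or design for channel ", bp$channels$name[ch],
              "; signed_r2 set to 0")
      return(0)
    }
    r <- stats::cor(x[ok], dd[ok])
    sign(r) * r^2
  }, numeric(1)) |> stats::setNames(bp$channels$name)
}

#' Select channels for onset analysis
#'
#' Channels qualify for a band's onset detection when they respond
#' significantly in that band's direction, lie inside the hand region, and
#' are labeled M1 or S1 (central-sulcus and other electrodes are deliberately
#' excluded from the timing comparison).
#'
#' @param stats a `channel_stats` data.frame from [test_task_response()].
#' @return character vector of qualifying channel names (possibly empty, with
#'   a warning: the onset stage is then skipped for this band).
#' @export
filter_analysis_channels <- function(stats) {
  stopifnot(inherits(stats, "channel_stats"))
  keep <- stats$significant & stats$in_hand_region & stats$region %in% c("M1", "S1")
  if (!any(keep)) {
    warning("no channel qualifies for band ", unique(stats$band),
            "; onset detection will be skipped")
  }
  stats$channel[keep]
}
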