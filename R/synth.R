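#' Configuration for the synthetic ECoG generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' 1/f-shaped broadband background, optional common 50 Hz line noise,
#' per-channel band-limited amplitude modulations (a 60-100 Hz increase and an
#' 8-30 Hz decrease) that begin at a fixed per-channel lag relative to the
#' true movement onset of each trial, per-trial reaction-time jitter shared by
#' all channels, bad channels, and a dataglove whose deflection follows the
#' true movement onset. Modulations are amplitude-modulated band-pass noise
#' (not pure tones), so wavelet band power rather than narrowband phase
#' carries the effect; the onset ramp is a raised cosine whose start defines
#' the ground-truth onset.
#'
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz.
#' @param n_trials_per_finger trials per finger (>= 1).
#' @param fingers finger labels.
#' @param region_of_channel region label per channel (M1/S1/CS/Other).
#' @param true_onset_s per-channel neural onset in seconds relative to the
#'   true movement onset (may be negative; must lie in [-1, 2]). `NA` marks a
#'   channel that carries no movement response (background only), emulating
#'   the many electrodes outside the hand region that real grids contribute
#'   to the common-average reference pool.
#' @param hfb_gain,lfb_gain dimensionless modulation depths (>= 0; the HFB
#'   carrier amplitude is multiplied by `1 + hfb_gain * r(t)`, the LFB carrier
#'   by `1 - lfb_gain * r(t)` with `r` the 0-1 response ramp; `lfb_gain <= 1`).
#' @param reaction_time_s mean cue-to-movement latency in seconds.
#' @param reaction_time_jitter_sd SD of the per-trial reaction-time jitter in
#'   seconds (applies to the whole trial: all channels shift together).
#' @param noise_exponent 1/f power-spectral slope of the background.
#' @param line_noise_amp amplitude of the common 50 Hz component.
#' @param bad_channel_ids indices of channels rendered bad (alternately flat
#'   and high-variance).
#' @param intertrial_range_s uniform bounds of the cue-to-cue interval.
#' @param rise_time_s raised-cosine rise time of the response ramp.
#' @param response_duration_s plateau duration of the response.
#' @param hfb_base_amp,lfb_base_amp baseline carrier amplitudes relative to
#'   the unit-SD background.
#' @param glove_noise_sd additive noise SD on the glove traces (flex units).
#' @param seed integer RNG seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 6,
                         fs = 512,
                         n_trials_per_finger = 30,
                         fingers = c("thumb", "index", "little"),
                         region_of_channel = rep(c("M1", "S1"), length.out = n_channels),
                         true_onset_s = rep(0, n_channels),
                         hfb_gain = 2,
                         lfb_gain = 0.5,
                         reaction_time_s = 0.4,
                         reaction_time_jitter_sd = 0.05,
                         noise_exponent = 2,
                         line_noise_amp = 1,
                         bad_channel_ids = integer(0),
                         intertrial_range_s = c(4.4, 5.0),
                         rise_time_s = 0.2,
                         response_duration_s = 1.0,
                         hfb_base_amp = 0.5,
                         lfb_base_amp = 1.0,
                         glove_noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(fs > 0, n_trials_per_finger >= 1, n_channels >= 1,
            length(fingers) >= 1, rise_time_s > 0)
  if (length(region_of_channel) != n_channels || length(true_onset_s) != n_channels) {
    stop("region_of_channel and true_onset_s must have length n_channels")
  }
  if (hfb_gain < 0 || lfb_gain < 0) stop("modulation gains must be non-negative")
  if (lfb_gain > 1) stop("lfb_gain must be <= 1 (power cannot become negative)")
  if (any(true_onset_s < -1 | true_onset_s > 2, na.rm = TRUE)) {
    stop("true onsets must lie within [-1, 2] s of movement onset")
  }
  if (!all(region_of_channel %in% REGION_LEVELS)) {
    stop("region_of_channel must be drawn from {", paste(REGION_LEVELS, collapse = ", "), "}")
  }
  structure(as.list(environment()), class = "synth_config")
}

# run expr with a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# unit-SD gaussian noise with power spectrum ~ 1/f^exponent. The brown-noise
# default (exponent 2) integrates white noise with a slow leak (fast, O(n));
# other exponents use FFT shaping clamped below 0.5 Hz to keep the variance
# finite.
.noise_one_over_f <- function(n, fs, exponent) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  if (exponent == 2) {
    # leaky integrator: 1-pole low-pass at ~0.5 Hz gives a 1/f^2 rolloff
    # above the corner without unbounded drift
    rho <- exp(-2 * pi * 0.5 / fs)
    y <- .iir_filter_cpp(1, c(1, -rho), matrix(x))[, 1]
    return(y / stats::sd(y))
  }
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency grid
  shape <- pmax(f, 0.5)^(-exponent / 2)
  shape[1] <- 0                        # remove DC
  y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

# unit-SD band-limited gaussian noise (single-pass Butterworth band edge
# filters; phase is irrelevant for a stochastic carrier)
.noise_bandpass <- function(n, fs, low, high) {
  x <- matrix(stats::rnorm(n))
  hp <- .butter(4, low, fs, "high")
  lp <- .butter(4, high, fs, "low")
  y <- .iir_filter_cpp(lp$b, lp$a, .iir_filter_cpp(hp$b, hp$a, x))[, 1]
  y / stats::sd(y)
}

# raised-cosine response ramp: 0 before 0, rises to 1 over `rise`, holds for
# `hold`, falls back over `rise`; ground-truth onset is the ramp start (t = 0)
.response_ramp <- function(t, rise, hold) {
  r <- numeric(length(t))
  up <- t > 0 & t < rise
  r[up] <- 0.5 * (1 - cos(pi * t[up] / rise))
  r[t >= rise & t <= rise + hold] <- 1
  dn <- t > rise + hold & t < 2 * rise + hold
  r[dn] <- 0.5 * (1 + cos(pi * (t[dn] - rise - hold) / rise))
  r
}

#' Generate a synthetic multichannel ECoG recording
#'
#' @param cfg a [synth_config()].
#' @return list with elements `recording` ([ecog_recording()]), `events`
#'   ([event_table()] of cue times; markers unset) and `truth`, a
#'   `synth_truth` list holding `true_movement_time_s` (per trial),
#'   `true_onset_s` and `region_of_channel` (per channel).
#' @details Deterministic for a fixed `cfg$seed`; the caller's RNG state is
#'   left untouched.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, {
    n_trials <- cfg$n_trials_per_finger * length(cfg$fingers)
    finger_seq <- sample(rep(cfg$fingers, cfg$n_trials_per_finger))
    gaps <- stats::runif(n_trials - 1, cfg$intertrial_range_s[1], cfg$intertrial_range_s[2])
    cue <- 3 + c(0, cumsum(gaps))
    move <- cue + cfg$reaction_time_s +
      stats::rnorm(n_trials, 0, cfg$reaction_time_jitter_sd)
    dur <- max(move) + 4
    n <- round(dur * cfg$fs)
    tgrid <- seq_len(n) / cfg$fs

    # per-trial response ramp, shifted per channel by its fixed onset lag
    ramp_len <- ceiling((2 * cfg$rise_time_s + cfg$response_duration_s) * cfg$fs)
    ramp_t <- seq_len(ramp_len) / cfg$fs
    base_ramp <- .response_ramp(ramp_t, cfg$rise_time_s, cfg$response_duration_s)

    line_phase <- stats::runif(1, 0, 2 * pi)
    line <- cfg$line_noise_amp * sin(2 * pi * 50 * tgrid + line_phase)

    sig <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      bg <- .noise_one_over_f(n, cfg$fs, cfg$noise_exponent)
      if (is.na(cfg$true_onset_s[ch])) {
        # background-only channel (contributes to CAR, carries no response)
        sig[ch, ] <- bg + line
        next
      }
      bh <- .noise_bandpass(n, cfg$fs, 60, 100)
      bl <- .noise_bandpass(n, cfg$fs, 8, 30)
      env <- numeric(n)
      starts <- round((move + cfg$true_onset_s[ch]) * cfg$fs)
      for (s0 in starts) {
        idx <- s0 + seq_len(ramp_len)
        ok <- idx >= 1 & idx <= n
        env[idx[ok]] <- pmax(env[idx[ok]], base_ramp[ok])
      }
      sig[ch, ] <- bg + line +
        cfg$hfb_base_amp * bh * (1 + cfg$hfb_gain * env) +
        cfg$lfb_base_amp * bl * (1 - cfg$lfb_gain * env)
    }

    for (k in seq_along(cfg$bad_channel_ids)) {
      ch <- cfg$bad_channel_ids[k]
      if (k %% 2 == 1) sig[ch, ] <- sig[ch, ] * 1e-4   # flat / broken lead
      else sig[ch, ] <- sig[ch, ] * 30                 # noisy
    }

    channels <- channel_table(
      name = sprintf("ch%02d", seq_len(cfg$n_channels)),
      region = cfg$region_of_channel
    )
    rec <- ecog_recording(sig, cfg$fs, channels)
    events <- event_table(seq_len(n_trials), finger_seq, cue)
    truth <- structure(list(true_movement_time_s = move,
                            true_onset_s = cfg$true_onset_s,
                            region_of_channel = cfg$region_of_channel),
                       class = "synth_truth")
    list(recording = rec, events = events, truth = truth)
  })
}

#' Generate synthetic dataglove traces
#'
#' One trace per finger; the moved finger deflects smoothly starting exactly
#' at the trial's true movement time (zero derivative before it), then
#' relaxes back to baseline.
#'
#' @param events [event_table()] from [generate_recording()].
#' @param truth matching `synth_truth`.
#' @param cfg the [synth_config()] used to generate the recording.
#' @return object of class `glove_trace`: list with `traces` (samples x
#'   fingers matrix), `fs` and `fingers`.
#' @export
generate_glove <- function(events, truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"),
            length(truth$true_movement_time_s) == nrow(events))
  .with_seed(cfg$seed + 1L, {
    dur <- max(truth$true_movement_time_s) + 4
    n <- round(dur * cfg$fs)
    shape_len <- ceiling(0.85 * cfg$fs)
    shape_t <- seq_len(shape_len) / cfg$fs
    # smooth sigmoid-like deflection: rise 0.15 s, hold 0.4 s, fall 0.3 s
    shape <- .response_ramp(shape_t, 0.15, 0.4)
    shape[shape_t > 0.55] <- 0.5 * (1 + cos(pi * pmin((shape_t[shape_t > 0.55] - 0.55) / 0.3, 1)))
    traces <- matrix(0, n, length(cfg$fingers))
    colnames(traces) <- cfg$fingers
    for (i in seq_len(nrow(events))) {
      f <- match(events$finger[i], cfg$fingers)
      s0 <- round(truth$true_movement_time_s[i] * cfg$fs)
      idx <- s0 + seq_len(shape_len)
      ok <- idx >= 1 & idx <= n
      traces[idx[ok], f] <- traces[idx[ok], f] + shape[ok]
    }
    if (cfg$glove_noise_sd > 0) {
      traces <- traces + matrix(stats::rnorm(length(traces), 0, cfg$glove_noise_sd),
                                nrow(traces))
    }
    structure(list(traces = traces, fs = cfg$fs, fingers = cfg$fingers),
              class = "glove_trace")
  })
}

#' @export
print.glove_trace <- function(x, ...) {
  cat(sprintf("<glove_trace> %d fingers x %d samples @ %g Hz\n",
              ncol(x$traces), nrow(x$traces), x$fs))
  invisible(x)
}
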