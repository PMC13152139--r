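#' Morlet wavelet kernel
#'
#' Complex Morlet wavelet at frequency `f`: a complex exponential under a
#' Gaussian envelope with time-domain SD `width / (2 * pi * f)` seconds,
#' truncated at `gwidth` SDs on each side and normalized to unit energy (so
#' the expected power response to unit-variance white noise is flat across
#' frequencies).
#'
#' @param f center frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param width wavelet width in cycles (SD of the Gaussian in cycle units).
#' @param gwidth kernel half-length in SDs of the Gaussian envelope.
#' @return complex vector of odd length.
#' @keywords internal
morlet_kernel <- function(f, fs, width = 7, gwidth = 3) {
  st <- width / (2 * pi * f)
  half <- max(1L, round(gwidth * st * fs))
  t <- seq.int(-half, half) / fs
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * st^2))
  k / sqrt(sum(Mod(k)^2))
}

#' Morlet time-frequency decomposition
#'
#' Squared-magnitude Morlet wavelet power per trial, channel, frequency bin
#' and time point. Edge samples within one kernel half-length of the epoch
#' boundary are invalidated (`NA`) per frequency, so baseline windows never
#' silently include edge artifacts.
#'
#' @param ts an [ecog_trialset()].
#' @param freqs frequencies in Hz (1 Hz steps by convention).
#' @param width,gwidth wavelet parameters, see [morlet_kernel()].
#' @return object of class `ecog_tfr`: list with `power` (trials x channels x
#'   freqs x time), `freqs`, `time_s`, `fs`, `finger`, `channels`, `trial_id`.
#' @export
morlet_power <- function(ts, freqs, width = 7, gwidth = 3) {
  stopifnot(inherits(ts, "ecog_trialset"))
  if (max(freqs) >= ts$fs / 2) {
    stop(sprintf("max frequency %g Hz must lie below the Nyquist frequency %g Hz",
                 max(freqs), ts$fs / 2))
  }
  d <- dim(ts$data)
  nt <- d[3]
  kernels <- lapply(freqs, morlet_kernel, fs = ts$fs, width = width, gwidth = gwidth)
  halves <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, integer(1))
  if (max(halves) * 2L >= nt) stop("epoch too short for the lowest-frequency wavelet")
  nfft <- stats::nextn(nt + 2L * max(halves), c(2, 3, 5))
  X <- matrix(0, nfft, d[1] * d[2])
  X[seq_len(nt), ] <- t(matrix(ts$data, d[1] * d[2], nt))
  FX <- stats::mvfft(X)
  pow <- array(NA_real_, c(d[1], d[2], length(freqs), nt))
  for (j in seq_along(freqs)) {
    k <- kernels[[j]]
    h <- halves[j]
    kf <- stats::fft(c(k, rep(0, nfft - length(k))))
    Y <- stats::mvfft(FX * kf, inverse = TRUE) / nfft
    # kernel is centered at tap h+1: convolution output aligned at lag h
    P <- Mod(Y[(h + 1L):(h + nt), , drop = FALSE])^2
    valid <- seq.int(h + 1L, nt - h)
    Pt <- matrix(NA_real_, nt, ncol(P))
    Pt[valid, ] <- P[valid, , drop = FALSE]
    pow[, , j, ] <- aperm(array(Pt, c(nt, d[1], d[2])), c(2, 3, 1))
  }
  structure(list(power = pow, freqs = freqs, time_s = ts$time_s, fs = ts$fs,
                 finger = ts$finger, channels = ts$channels, trial_id = ts$trial_id),
            class = "ecog_tfr")
}

#' Average a time-frequency decomposition over a band
#'
#' Arithmetic mean over the band's 1 Hz bins, endpoints inclusive. A time
#' sample is `NA` if any contributing bin is edge-invalidated there, so the
#' band trace inherits the widest (lowest-frequency) kernel's edge margin.
#'
#' @param tfr an `ecog_tfr` from [morlet_power()].
#' @param band a [band_spec()].
#' @return a [band_power()].
#' @export
band_average <- function(tfr, band) {
  stopifnot(inherits(tfr, "ecog_tfr"), inherits(band, "band_spec"))
  sel <- which(tfr$freqs >= band$low - 1e-9 & tfr$freqs <= band$high + 1e-9)
  if (length(sel) == 0L) stop("band ", band$name, " has no computed frequency bins")
  d <- dim(tfr$power)
  sub <- tfr$power[, , sel, , drop = FALSE]
  avg <- apply(sub, c(1, 2, 4), mean)   # NA propagates: strict edge handling
  band_power(avg, tfr$time_s, tfr$fs, tfr$finger, tfr$channels, band, tfr$trial_id)
}

#' Band-averaged Morlet power (fused fast path)
#'
#' Computes the same quantity as [morlet_power()] followed by
#' [band_average()] over the band's 1 Hz bins, via direct strided convolution
#' in C++ without materializing the full time-frequency array. With
#' `stride > 1` power is evaluated every `stride` samples (FieldTrip-style
#' output decimation); edge invalidation uses the widest kernel in the band
#' uniformly, matching the strict `NA` propagation of [band_average()].
#'
#' @param ts an [ecog_trialset()].
#' @param band a [band_spec()]; bins are `seq(band$low, band$high)` (1 Hz).
#' @param width,gwidth wavelet parameters.
#' @param stride output time stride in samples (>= 1).
#' @return a [band_power()] whose time axis is `ts$time_s[seq(1, nt, stride)]`.
#' @export
band_power_morlet <- function(ts, band, width = 7, gwidth = 3, stride = 1L) {
  stopifnot(inherits(ts, "ecog_trialset"), inherits(band, "band_spec"), stride >= 1)
  freqs <- seq(band$low, band$high, by = 1)
  if (max(freqs) >= ts$fs / 2) {
    stop(sprintf("max frequency %g Hz must lie below the Nyquist frequency %g Hz",
                 max(freqs), ts$fs / 2))
  }
  d <- dim(ts$data)
  nt <- d[3]
  kernels <- lapply(freqs, morlet_kernel, fs = ts$fs, width = width, gwidth = gwidth)
  if ((length(kernels[[1]]) - 1L) >= nt) stop("epoch too short for the lowest-frequency wavelet")
  X <- t(matrix(ts$data, d[1] * d[2], nt))   # time x (trial*channel)
  P <- .morlet_band_power_cpp(X, lapply(kernels, Re), lapply(kernels, Im),
                              as.integer(stride))
  keep_t <- seq.int(1L, nt, by = stride)
  out <- aperm(array(P, c(length(keep_t), d[1], d[2])), c(2, 3, 1))
  band_power(out, ts$time_s[keep_t], ts$fs / stride, ts$finger, ts$channels,
             band, ts$trial_id)
}
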