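# IIR filter design and zero-phase filtering.
#
# Small, self-contained Butterworth / biquad designs (bilinear transform with
# prewarping) plus a forward-backward filter with odd-reflection padding.
# Onset latency is the measurand throughout the package, so every filter is
# applied zero-phase.

# expand a polynomial from its roots (complex), return real coefficients
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  Re(p)
}

# Butterworth low/high-pass (b, a) at cutoff_hz for sampling rate fs
.butter <- function(n, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(n >= 1, cutoff_hz > 0, cutoff_hz < fs / 2)
  w <- 2 * fs * tan(pi * cutoff_hz / fs)  # prewarped analog cutoff (rad/s)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane poles
  if (type == "low") {
    pa <- w * proto
    za <- complex(0)
    ka <- w^n
  } else {
    pa <- w / proto
    za <- rep(0 + 0i, n)
    ka <- 1
  }
  fs2 <- 2 * fs
  pd <- (fs2 + pa) / (fs2 - pa)
  zd <- c((fs2 + za) / (fs2 - za), rep(-1 + 0i, length(pa) - length(za)))
  kd <- Re(ka * prod(fs2 - za) / prod(fs2 - pa))
  list(b = kd * .poly_from_roots(zd), a = .poly_from_roots(pd))
}

# RBJ-cookbook notch biquad centered at f0_hz with quality factor q
.notch_biquad <- function(f0_hz, fs, q) {
  w0 <- 2 * pi * f0_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# single-pass IIR filter of each column of X (time x series)
.iir_filter_mat <- function(b, a, X) {
  X <- as.matrix(X)
  .iir_filter_cpp(b / a[1], a / a[1], X)
}

# zero-phase (forward-backward) filtering with odd-reflection edge padding
.filtfilt_mat <- function(b, a, X, npad = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(npad)) npad <- 3L * (max(length(a), length(b)) - 1L)
  npad <- min(npad, n - 1L)
  if (npad > 0L) {
    head_pad <- 2 * rep(X[1, ], each = npad) - X[(npad + 1L):2L, , drop = FALSE]
    tail_pad <- 2 * rep(X[n, ], each = npad) - X[(n - 1L):(n - npad), , drop = FALSE]
    dim(head_pad) <- c(npad, ncol(X)); dim(tail_pad) <- c(npad, ncol(X))
    Xp <- rbind(head_pad, X, tail_pad)
  } else {
    Xp <- X
  }
  Y <- .iir_filter_mat(b, a, Xp)
  Y <- .iir_filter_mat(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(npad + 1L):(npad + n), , drop = FALSE]
}
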