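# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# small recording with known per-channel content
tiny_recording <- function(n_channels = 4, fs = 512, dur_s = 10,
                           regions = rep(c("M1", "S1"), length.out = n_channels),
                           gen = function(ch, t) rnorm(length(t))) {
  t <- seq_len(round(dur_s * fs)) / fs
  sig <- t(vapply(seq_len(n_channels), function(ch) gen(ch, t), numeric(length(t))))
  ecog_recording(sig, fs, channel_table(sprintf("ch%02d", seq_len(n_channels)), regions))
}

# band power object built directly from an array (bypasses the wavelet)
tiny_band_power <- function(data, fs = 20, band = band_spec("hfb", 60, 100),
                            time0 = -1, fingers = "thumb",
                            regions = rep(c("M1", "S1"), length.out = dim(data)[2])) {
  d <- dim(data)
  band_power(data, time0 + (seq_len(d[3]) - 1) / fs, fs,
             rep_len(fingers, d[1]),
             channel_table(sprintf("ch%02d", seq_len(d[2])), regions), band)
}

# onset_traces built directly from a channels x time matrix
tiny_traces <- function(traces, fs = 64, band = band_spec("hfb", 60, 100),
                        time0 = -1,
                        regions = rep(c("M1", "S1"), length.out = nrow(traces))) {
  nt <- ncol(traces)
  onset_traces(traces, time0 + (seq_len(nt) - 1) / fs, band,
               channel_table(sprintf("ch%02d", seq_len(nrow(traces))), regions),
               finger = "thumb", fs = fs)
}

# Independent brute-force oracle for the two-phase threshold rule: literal
# enumeration over the grid, no shared code with optimize_threshold().
oracle_threshold <- function(traces, time_s, direction, start = 0.4, step = 0.1,
                             window = c(-0.5, 0.5), spare = 2, phase2 = TRUE) {
  d <- if (direction == "increase") 1 else -1
  D <- d * traces
  v_at <- apply(D, 1, function(y) approx(time_s, y, xout = window[1], rule = 2)$y)
  win <- time_s >= window[1] & time_s <= window[2]
  reaches <- function(th) {
    sum(apply(D[, win, drop = FALSE], 1, function(y) any(y >= th, na.rm = TRUE)))
  }
  grid <- seq(start, start + 400 * step, by = step)
  # phase 1: first grid value above the window-start level of all but `spare`
  p1 <- NA
  for (th in grid) {
    if (sum(v_at >= th) <= spare) { p1 <- th; break }
  }
  if (!phase2) return(d * p1)
  # nothing reaches the phase-1 value: it is returned unchanged
  if (reaches(p1) == 0) return(d * p1)
  # phase 2: walk up while the reach count does not decrease
  counts <- vapply(grid, reaches, numeric(1))
  i <- match(p1, grid)
  while (i < length(grid) && counts[i + 1] >= counts[i]) i <- i + 1
  d * grid[i]
}

# quick paired-window band power fixture with an injected post-marker step
stepped_band_power <- function(n_trials = 20, n_channels = 2, fs = 20,
                               effect = c(1, 0), noise_sd = 0.5, seed = 1,
                               band = band_spec("hfb", 60, 100)) {
  set.seed(seed)
  time_s <- seq(-1, 2, by = 1 / fs)
  dat <- array(abs(rnorm(n_trials * n_channels * length(time_s), 10, noise_sd)),
               c(n_trials, n_channels, length(time_s)))
  for (ch in seq_len(n_channels)) {
    dat[, ch, time_s >= 0] <- dat[, ch, time_s >= 0] + effect[ch]
  }
  tiny_band_power(dat, fs = fs, band = band)
}
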