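test_that("bad-channel screening flags flat and noisy channels, spares clean ones", {
  set.seed(1)
  rec <- tiny_recording(6, dur_s = 4)
  rec$signal[2, ] <- 0                     # broken lead
  rec$signal[5, ] <- rec$signal[5, ] * 10  # variance 100x the median
  out <- detect_bad_channels(rec)
  expect_identical(which(out$channels$bad), c(2L, 5L))

  clean <- detect_bad_channels(tiny_recording(6, dur_s = 4))
  expect_false(any(clean$channels$bad))

  flat <- tiny_recording(3, dur_s = 2, gen = function(ch, t) rep(0, length(t)))
  expect_error(detect_bad_channels(flat), "all channels")

  manual <- detect_bad_channels(tiny_recording(4, dur_s = 2), manual_bad = "ch03")
  expect_true(manual$channels$bad[3])
})

test_that("CAR zeroes identical channels and conserves the pool mean", {
  set.seed(2)
  x <- rnorm(1000)
  rec <- ecog_recording(rbind(x, x), 512, channel_table(c("a", "b"), c("M1", "S1")))
  out <- common_average_reference(rec)
  expect_equal(max(abs(out$signal)), 0)

  rec6 <- tiny_recording(6, dur_s = 2)
  out6 <- common_average_reference(rec6)
  expect_lt(max(abs(colMeans(out6$signal))), 1e-12)

  # bad channels stay out of the pool
  rec6$channels$bad[1] <- TRUE
  out_b <- common_average_reference(rec6)
  expect_lt(max(abs(colMeans(out_b$signal[-1, , drop = FALSE]))), 1e-12)

  one <- tiny_recording(3, dur_s = 1)
  one$channels$in_car <- c(TRUE, FALSE, FALSE)
  expect_error(common_average_reference(one), "at least 2")
})

test_that("CAR removes a common 50 Hz component", {
  set.seed(3)
  fs <- 512
  t <- seq_len(4 * fs) / fs
  line <- 5 * sin(2 * pi * 50 * t)
  rec <- tiny_recording(4, fs = fs, dur_s = 4,
                        gen = function(ch, t) rnorm(length(t)) + 5 * sin(2 * pi * 50 * t))
  p50 <- function(x) mean(spec.pgram(ts(x, frequency = fs), plot = FALSE,
                                     spans = 5)$spec[abs(spec.pgram(ts(x, frequency = fs),
                                                                    plot = FALSE, spans = 5)$freq - 50) < 1])
  before <- p50(rec$signal[1, ])
  after <- p50(common_average_reference(rec)$signal[1, ])
  expect_lt(after, before / 100)
})

test_that("equalizing filter attenuates 50 Hz, passes 80 Hz, removes DC", {
  fs <- 512
  t <- seq_len(10 * fs) / fs
  mid <- fs:(9 * fs)
  mk <- function(x) ecog_recording(rbind(x, x), fs, channel_table(c("a", "b"), c("M1", "S1")))
  for (probe in list(c(50, -20), c(80, -1))) {
    x <- sin(2 * pi * probe[1] * t)
    y <- equalize_filter(mk(x))$signal[1, ]
    att <- 10 * log10(mean(y[mid]^2) / mean(x[mid]^2))
    if (probe[1] == 50) expect_lt(att, probe[2]) else expect_gt(att, probe[2])
  }
  dc <- equalize_filter(mk(rep(10, length(t))))$signal[1, mid]
  expect_lt(abs(mean(dc)), 0.1)   # 10-unit offset suppressed below the 0.15 Hz corner

  lowfs <- ecog_recording(matrix(rnorm(500), 2), 250, channel_table(c("a", "b"), c("M1", "S1")))
  expect_error(equalize_filter(lowfs), "Nyquist")
})

test_that("filtering is idempotent for in-band content", {
  # the 0.15 Hz corner has a ~1 s edge transient, so judge well away from
  # the signal edges (continuous recordings are hundreds of seconds long)
  fs <- 512
  t <- seq_len(16 * fs) / fs
  x <- sin(2 * pi * 20 * t)
  rec <- ecog_recording(rbind(x, x), fs, channel_table(c("a", "b"), c("M1", "S1")))
  once <- equalize_filter(rec)
  twice <- equalize_filter(once)
  mid <- (5 * fs):(11 * fs)
  # sample tolerance reflects the slowly-decaying 0.15 Hz edge transient
  expect_equal(twice$signal[1, mid], once$signal[1, mid], tolerance = 0.02)
  # in-band amplitude is preserved to much finer tolerance
  expect_equal(sqrt(mean(twice$signal[1, mid]^2)) / sqrt(mean(once$signal[1, mid]^2)),
               1, tolerance = 1e-3)
})

test_that("epoching aligns to markers with the documented endpoint rule", {
  fs <- 512
  rec <- tiny_recording(3, fs = fs, dur_s = 150, regions = c("M1", "S1", "CS"))
  cues <- seq(5, 149 - 5, length.out = 30)
  ev <- event_table(1:30, "thumb", cues, cues + 0.3)
  ts <- epoch_trials(rec, ev, c(-1, 2))
  expect_equal(dim(ts$data), c(30, 3, round(3 * fs) + 1))
  expect_equal(ts$time_s[1], -1)
  expect_equal(ts$time_s[length(ts$time_s)], 2)
  expect_equal(ts$time_s[which(ts$time_s == 0)], 0)

  # round-trip: trial samples match the raw recording slices exactly
  i <- 7
  start <- round(ev$marker_time_s[i] * fs) + round(-1 * fs)
  expect_identical(ts$data[i, 2, ], rec$signal[2, start:(start + round(3 * fs))])

  # an event too close to the recording edge is dropped with a warning
  ev2 <- event_table(1:2, "thumb", c(0.5, 10), c(0.5, 10))
  expect_warning(ts2 <- epoch_trials(rec, ev2, c(-1, 2)), "dropped")
  expect_equal(dim(ts2$data)[1], 1)

  # missing marker names the trial
  ev3 <- event_table(1:2, "thumb", c(10, 20), c(10, NA))
  expect_error(epoch_trials(rec, ev3, c(-1, 2)), "2")
})

test_that("epoching drops bad channels and excluded trials", {
  rec <- tiny_recording(4, dur_s = 30)
  rec$channels$bad[2] <- TRUE
  ev <- event_table(1:3, "thumb", c(5, 10, 15), c(5, 10, 15), excluded = c(FALSE, TRUE, FALSE))
  ts <- epoch_trials(rec, ev, c(-1, 2))
  expect_equal(dim(ts$data)[1:2], c(2L, 3L))
  expect_identical(ts$channels$name, c("ch01", "ch03", "ch04"))
  expect_identical(ts$trial_id, c(1L, 3L))
})

test_that("trial rejection removes manual exclusions and artifact spikes", {
  set.seed(4)
  dat <- array(rnorm(20 * 2 * 61), c(20, 2, 61))
  ts <- ecog_trialset(dat, seq(-1, 2, by = 0.05), 20, rep("thumb", 20),
                      channel_table(c("a", "b"), c("M1", "S1")))
  expect_identical(reject_trials(ts)$trial_id, ts$trial_id)   # clean: no change

  dat2 <- dat
  dat2[7, 1, 30] <- 50                      # ~50 SD spike
  ts2 <- ecog_trialset(dat2, ts$time_s, 20, ts$finger, ts$channels)
  expect_message(out <- reject_trials(ts2), "dropped 1")
  expect_false(7L %in% out$trial_id)

  expect_message(out2 <- reject_trials(ts, manual_exclusions = c(3, 5)), "2 manual")
  expect_identical(setdiff(ts$trial_id, out2$trial_id), c(3L, 5L))

  expect_error(reject_trials(ts, manual_exclusions = 1:20), "all trials")
})
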