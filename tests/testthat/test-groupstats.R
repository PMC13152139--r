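mk_onsets <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$band)) df$band <- "hfb"
  if (is.null(df$finger)) df$finger <- "thumb"
  if (is.null(df$channel)) df$channel <- sprintf("ch%02d", seq_len(nrow(df)))
  class(df) <- c("onset_table", "data.frame")
  df
}

# a printed toy table: 3 participants x 2 regions x 3 fingers
toy_cells <- function() {
  expand.grid(participant = c("P1", "P2", "P3"),
              region = c("M1", "S1"),
              finger = c("thumb", "index", "little"),
              stringsAsFactors = FALSE) |>
    transform(y = c(
      0.10, 0.12, 0.08,   0.22, 0.25, 0.19,   # thumb  M1 / S1
      0.11, 0.15, 0.09,   0.20, 0.28, 0.16,   # index
      0.13, 0.10, 0.07,   0.24, 0.21, 0.18))  # little
}

toy_summary <- function() {
  cells <- toy_cells()
  wide <- reshape(cells, idvar = c("participant", "finger"), timevar = "region",
                  direction = "wide")
  out <- data.frame(participant = wide$participant, finger = wide$finger,
                    band = "hfb", mean_onset_M1 = wide$y.M1,
                    mean_onset_S1 = wide$y.S1, n_M1 = 5, n_S1 = 5)
  class(out) <- c("region_summary", "data.frame")
  out
}

test_that("region summaries are plain cell means with NA for empty cells", {
  on <- mk_onsets(participant = "P1",
                  region = c("M1", "M1", "S1"),
                  onset_s = c(0.1, 0.2, 0.3))
  rs <- summarize_regions(on)
  expect_equal(rs$mean_onset_M1, 0.15)
  expect_equal(rs$mean_onset_S1, 0.3)
  expect_equal(c(rs$n_M1, rs$n_S1), c(2L, 1L))

  on2 <- mk_onsets(participant = "P1", region = c("M1", "M1"), onset_s = c(0.1, 0.2))
  rs2 <- summarize_regions(on2)
  expect_true(is.na(rs2$mean_onset_S1))
  expect_equal(rs2$n_S1, 0L)
})

test_that("repeated-measures ANOVA matches the aov() sums-of-squares oracle", {
  rs <- toy_summary()
  fit <- region_anova(rs)
  cells <- toy_cells()
  cells$participant <- factor(cells$participant)
  cells$region <- factor(cells$region)
  cells$finger <- factor(cells$finger)
  oracle <- summary(aov(y ~ region * finger + Error(participant / (region * finger)),
                        data = cells))
  getF <- function(stratum, term) {
    tb <- oracle[[stratum]][[1]]
    tb[trimws(rownames(tb)) == term, "F value"]
  }
  expect_equal(fit$effects$F[fit$effects$effect == "region"],
               getF("Error: participant:region", "region"), tolerance = 1e-10)
  expect_equal(fit$effects$F[fit$effects$effect == "finger"],
               getF("Error: participant:finger", "finger"), tolerance = 1e-10)
  expect_equal(fit$effects$F[fit$effects$effect == "region:finger"],
               getF("Error: participant:region:finger", "region:finger"),
               tolerance = 1e-10)
  expect_equal(fit$effects$df1, c(1, 2, 2))
  expect_equal(fit$effects$df2, c(2, 4, 4))
  # two-level factor: post-hoc t^2 equals the region F, Tukey p equals raw p
  ph <- fit$posthoc[fit$posthoc$factor == "region", ]
  expect_equal(ph$t^2, fit$effects$F[1], tolerance = 1e-10)
  expect_equal(ph$estimate, mean(rs$mean_onset_M1) - mean(rs$mean_onset_S1))
})

test_that("identical cell values give F = 0 throughout", {
  rs <- toy_summary()
  rs$mean_onset_M1 <- 0.2
  rs$mean_onset_S1 <- 0.2
  fit <- region_anova(rs)
  expect_equal(fit$effects$F, c(0, 0, 0))
})

test_that("participants with incomplete cells are dropped listwise", {
  rs <- toy_summary()
  rs$mean_onset_S1[rs$participant == "P3" & rs$finger == "index"] <- NA
  expect_warning(fit <- region_anova(rs), "P3")
  expect_equal(fit$n_participants, 2)
  rs2 <- rs[rs$participant == "P1", ]
  class(rs2) <- class(rs)
  expect_error(region_anova(rs2), "at least 2")
})

test_that("the lmer route reproduces the classical F for balanced data", {
  skip_if_not_installed("lme4")
  rs <- toy_summary()
  classical <- region_anova(rs)
  mixed <- suppressMessages(region_anova(rs, method = "lmer"))
  # fixed-effect F ratios agree for balanced complete designs up to the
  # error-term convention; the region effect must match in sign and scale
  expect_equal(sign(mixed$posthoc$estimate[1]), sign(classical$posthoc$estimate[1]))
  expect_true(is.finite(mixed$effects$F[1]))
})

test_that("synthetic region effect is recovered by the ANOVA (power check)", {
  set.seed(50)
  hits <- vapply(1:30, function(i) {
    rs <- do.call(rbind, lapply(1:8, function(p) {
      data.frame(participant = sprintf("P%d", p), finger = c("thumb", "index", "little"),
                 band = "hfb",
                 mean_onset_M1 = rnorm(3, 0.30, 0.04),
                 mean_onset_S1 = rnorm(3, 0.40, 0.04),
                 n_M1 = 3, n_S1 = 3)
    }))
    class(rs) <- c("region_summary", "data.frame")
    fit <- region_anova(rs)
    fit$effects$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("per-participant Welch tests exclude small participants from the correction", {
  set.seed(51)
  onsets <- rbind(
    mk_onsets(participant = "P1", region = rep(c("M1", "S1"), each = 6),
              onset_s = c(rnorm(6, 0.10, 0.05), rnorm(6, 0.25, 0.05)),
              channel = sprintf("a%02d", 1:12)),
    mk_onsets(participant = "P2", region = rep(c("M1", "S1"), each = 6),
              onset_s = rep(0.2, 12) + rnorm(12, 0, 0.01),
              channel = sprintf("b%02d", 1:12)),
    mk_onsets(participant = "P3", region = c("M1", "M1", "S1", "S1", "S1"),
              onset_s = c(0.1, 0.12, 0.3, 0.31, 0.29),
              channel = sprintf("c%02d", 1:5))
  )
  res <- per_participant_tests(onsets)
  expect_false(res$tested[res$participant == "P3"])     # only 2 M1 channels
  expect_true(all(is.na(res$p_bonferroni[res$participant == "P3"])))
  tested <- res[res$tested, ]
  expect_equal(nrow(tested), 2)
  expect_equal(tested$p_bonferroni, pmin(1, tested$p_raw * 2))  # factor = tested count
  expect_true(res$significant[res$participant == "P1"])
  expect_false(res$significant[res$participant == "P2"])  # identical distributions
})

test_that("Welch separation is detected reliably at the documented effect size", {
  set.seed(52)
  hits <- vapply(1:50, function(i) {
    on <- mk_onsets(participant = "P1", region = rep(c("M1", "S1"), each = 10),
                    onset_s = c(rnorm(10, 0.10, 0.05), rnorm(10, 0.25, 0.05)),
                    channel = sprintf("c%02d", 1:20))
    per_participant_tests(on)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("earliest-quartile percentage handles the printed enumerations", {
  # 12 channels, earliest 3 are M1 -> 100%
  on <- mk_onsets(region = c(rep("M1", 3), rep(c("M1", "S1"), c(3, 6))),
                  onset_s = c(1:3 / 100, 4:12 / 10))
  expect_equal(earliest_quartile_pct(on), 100)

  # alternating onsets -> about 50%
  on2 <- mk_onsets(region = rep(c("M1", "S1"), 8), onset_s = seq(0.01, 0.16, by = 0.01))
  expect_equal(earliest_quartile_pct(on2), 50)

  # 8 + 8 with all M1 earlier -> 100%
  on3 <- mk_onsets(region = rep(c("M1", "S1"), each = 8),
                   onset_s = c(1:8 / 100, 9:16 / 10))
  expect_equal(earliest_quartile_pct(on3), 100)

  # boundary ties are all included: quartile of 8 is 2, but three tie at the cut
  on4 <- mk_onsets(region = c("M1", "S1", "M1", rep("S1", 5)),
                   onset_s = c(0.1, 0.1, 0.1, 0.4, 0.5, 0.6, 0.7, 0.8))
  expect_equal(earliest_quartile_pct(on4), 100 * 2 / 3)

  expect_error(earliest_quartile_pct(mk_onsets(region = "M1", onset_s = 0.1)),
               "at least 4")
})

test_that("earliest-quartile percentage matches exhaustive enumeration on random tables", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(4:16, 1)
    on <- mk_onsets(region = sample(c("M1", "S1"), n, replace = TRUE),
                    onset_s = round(runif(n), 2))   # rounding forces occasional ties
    got <- earliest_quartile_pct(on)
    q <- ceiling(n / 4)
    cut <- sort(on$onset_s)[q]
    sel <- which(on$onset_s <= cut)
    want <- 100 * sum(on$region[sel] == "M1") / length(sel)
    expect_equal(got, want)
    expect_gte(got, 0); expect_lte(got, 100)
  }
})

test_that("earliest channel is returned with documented tie handling", {
  on <- mk_onsets(region = c("S1", "M1", "M1"), onset_s = c(0.2, 0.05, 0.4))
  expect_equal(earliest_channel(on)$channel, "ch02")
  expect_equal(earliest_channel(on)$region, "M1")

  tie <- mk_onsets(region = c("M1", "S1"), onset_s = c(0.1, 0.1))
  expect_message(res <- earliest_channel(tie), "tie")
  expect_equal(res$channel, "ch01")
})

test_that("grouped summaries return one row per cell", {
  on <- rbind(
    mk_onsets(participant = "P1", finger = "thumb", region = rep(c("M1", "S1"), each = 4),
              onset_s = 1:8 / 10, channel = sprintf("a%d", 1:8)),
    mk_onsets(participant = "P2", finger = "thumb", region = rep(c("S1", "M1"), each = 4),
              onset_s = 1:8 / 10, channel = sprintf("b%d", 1:8))
  )
  q <- earliest_quartile_pct(on, by = "participant")
  expect_equal(nrow(q), 2)
  expect_equal(q$pct[q$participant == "P1"], 100)
  expect_equal(q$pct[q$participant == "P2"], 0)
  ec <- earliest_channel(on, by = "participant")
  expect_equal(nrow(ec), 2)
})
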