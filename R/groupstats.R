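#' Per-participant region summaries of neural onsets
#'
#' Averages onset times separately per participant, finger, band and cortical
#' region (M1 vs S1). Empty cells are reported as `NA`, never as zero.
#'
#' @param onsets an `onset_table` with a `participant` column (see
#'   [detect_onsets()]; cohort runners add `participant`).
#' @return data.frame of class `region_summary` with one row per
#'   participant x finger x band and columns `mean_onset_M1`, `mean_onset_S1`,
#'   `n_M1`, `n_S1`.
#' @export
summarize_regions <- function(onsets) {
  onsets <- .require_onset_cols(onsets)
  onsets <- onsets[onsets$region %in% c("M1", "S1"), , drop = FALSE]
  cells <- unique(onsets[, c("participant", "finger", "band")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- merge(cells[i, ], onsets)
    m1 <- sub$onset_s[sub$region == "M1"]
    s1 <- sub$onset_s[sub$region == "S1"]
    data.frame(cells[i, ],
               mean_onset_M1 = if (length(m1)) mean(m1) else NA_real_,
               mean_onset_S1 = if (length(s1)) mean(s1) else NA_real_,
               n_M1 = length(m1), n_S1 = length(s1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_summary", "data.frame")
  out
}

.require_onset_cols <- function(onsets) {
  need <- c("participant", "finger", "band", "region", "onset_s")
  miss <- setdiff(need, names(onsets))
  if (length(miss)) stop("onset table lacks column(s): ", paste(miss, collapse = ", "))
  onsets
}

#' Two-within-factor repeated-measures ANOVA on region means
#'
#' Compares mean neural onsets with cortical region (M1/S1) and finger as
#' within-subject factors and participant as the repeated-measures grouping
#' factor. The default is the classical repeated-measures decomposition
#' computed from sums of squares (each effect tested against its own
#' effect-by-subject interaction), which coincides with the mixed-model
#' ANOVA for balanced complete data; `method = "lmer"` fits
#' `lme4::lmer(onset ~ region * finger + (1 | participant))` instead and
#' reports F ratios with the classical degrees of freedom. Post-hoc pairwise
#' comparisons of marginal means use Tukey adjustment (studentized range on
#' the matching error term). Participants with incomplete cells are dropped
#' listwise with a warning.
#'
#' @param rs a `region_summary` from [summarize_regions()].
#' @param band which band to analyze (required if several are present).
#' @param method `"rm"` (classical, default) or `"lmer"`.
#' @return object of class `region_anova`: list with `effects` (data.frame of
#'   F, df, p per effect), `posthoc` (marginal-mean contrasts with
#'   Tukey-adjusted p), `n_participants`, `band`, `method`.
#' @export
region_anova <- function(rs, band = NULL, method = c("rm", "lmer")) {
  method <- match.arg(method)
  stopifnot(inherits(rs, "region_summary"))
  if (is.null(band)) {
    band <- unique(rs$band)
    if (length(band) > 1) stop("several bands present; pick one via `band`")
  }
  rs <- rs[rs$band == band, , drop = FALSE]
  long <- rbind(
    data.frame(participant = rs$participant, finger = rs$finger,
               region = "M1", y = rs$mean_onset_M1),
    data.frame(participant = rs$participant, finger = rs$finger,
               region = "S1", y = rs$mean_onset_S1)
  )
  fingers <- sort(unique(long$finger))
  # listwise exclusion: participants must have all region x finger cells
  complete <- vapply(split(long, long$participant), function(d) {
    !anyNA(d$y) && nrow(d) == 2 * length(fingers)
  }, logical(1))
  if (any(!complete)) {
    warning("excluding participant(s) with incomplete cells: ",
            paste(names(complete)[!complete], collapse = ", "))
  }
  long <- long[long$participant %in% names(complete)[complete], , drop = FALSE]
  subj <- sort(unique(long$participant))
  n <- length(subj); a <- 2L; b <- length(fingers)
  if (n < 2) stop("need at least 2 participants with complete cells")

  y <- array(NA_real_, c(n, a, b))
  for (i in seq_len(nrow(long))) {
    y[match(long$participant[i], subj),
      match(long$region[i], c("M1", "S1")),
      match(long$finger[i], fingers)] <- long$y[i]
  }

  gm <- mean(y)
  mA <- apply(y, 2, mean); mB <- apply(y, 3, mean); mS <- apply(y, 1, mean)
  mAB <- apply(y, c(2, 3), mean); mAS <- apply(y, c(1, 2), mean)
  mBS <- apply(y, c(1, 3), mean)
  ssA <- n * b * sum((mA - gm)^2)
  ssB <- n * a * sum((mB - gm)^2)
  ssAB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
  ssAS <- b * sum((mAS - outer(mS, mA, `+`) + gm)^2)
  ssBS <- a * sum((mBS - outer(mS, mB, `+`) + gm)^2)
  resid <- y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b)) {
    resid[i, j, k] <- y[i, j, k] - mAS[i, j] - mBS[i, k] - mAB[j, k] +
      mS[i] + mA[j] + mB[k] - gm
  }
  ssABS <- sum(resid^2)
  dfA <- a - 1L; dfB <- b - 1L; dfAB <- dfA * dfB
  dfAS <- dfA * (n - 1L); dfBS <- dfB * (n - 1L); dfABS <- dfAB * (n - 1L)
  eff <- data.frame(
    effect = c("region", "finger", "region:finger"),
    df1 = c(dfA, dfB, dfAB),
    df2 = c(dfAS, dfBS, dfABS),
    ss = c(ssA, ssB, ssAB),
    ss_error = c(ssAS, ssBS, ssABS),
    stringsAsFactors = FALSE
  )
  # a zero effect sum of squares is F = 0 even when the error term is also
  # degenerate (all cell values identical)
  eff$F <- ifelse(eff$ss <= 1e-12 * max(1, abs(gm)),
                  0, (eff$ss / eff$df1) / (eff$ss_error / eff$df2))
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)

  if (method == "lmer") {
    if (!requireNamespace("lme4", quietly = TRUE)) stop("method 'lmer' needs the lme4 package")
    fit <- lme4::lmer(y ~ region * finger + (1 | participant), data = long, REML = TRUE)
    av <- stats::anova(fit)
    eff$F <- av[["F value"]][match(c("region", "finger", "region:finger"), rownames(av))]
    eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  }

  # post-hoc: Tukey-adjusted marginal-mean contrasts against the matching
  # within-subject error term (studentized range; for 2 levels this reduces
  # to the paired comparison)
  msAS <- ssAS / dfAS; msBS <- ssBS / dfBS
  ph <- list()
  ph[[1]] <- data.frame(
    factor = "region", contrast = "M1 - S1",
    estimate = mA[1] - mA[2],
    se = sqrt(2 * msAS / (n * b)),
    df = dfAS, stringsAsFactors = FALSE
  )
  cmb <- utils::combn(b, 2)
  for (kk in seq_len(ncol(cmb))) {
    i1 <- cmb[1, kk]; i2 <- cmb[2, kk]
    ph[[length(ph) + 1]] <- data.frame(
      factor = "finger", contrast = paste(fingers[i1], "-", fingers[i2]),
      estimate = mB[i1] - mB[i2],
      se = sqrt(2 * msBS / (n * a)),
      df = dfBS, stringsAsFactors = FALSE
    )
  }
  ph <- do.call(rbind, ph)
  ph$t <- ph$estimate / ph$se
  nm <- ifelse(ph$factor == "region", a, b)
  # studentized range needs df >= 2; below that (and exactly for 2 means)
  # the Tukey-adjusted p equals the two-sided t-test p
  use_range <- ph$df >= 2 & nm > 2
  ph$p_tukey <- 2 * stats::pt(-abs(ph$t), ph$df)
  if (any(use_range)) {
    ph$p_tukey[use_range] <- stats::ptukey(sqrt(2) * abs(ph$t[use_range]),
                                           nm[use_range], ph$df[use_range],
                                           lower.tail = FALSE)
  }

  structure(list(effects = eff[, c("effect", "df1", "df2", "F", "p")],
                 posthoc = ph, n_participants = n, band = band, method = method),
            class = "region_anova")
}

#' @export
print.region_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s onsets (%d participants, method %s)\n",
              x$band, x$n_participants, x$method))
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    cat(sprintf("  %-14s F(%d,%d) = %.3f, p = %.4g\n", e$effect, e$df1, e$df2, e$F, e$p))
  }
  cat("Post-hoc (Tukey-adjusted):\n")
  for (i in seq_len(nrow(x$posthoc))) {
    p <- x$posthoc[i, ]
    cat(sprintf("  %-8s %-16s est = %+.4f s, t(%d) = %.2f, p = %.4g\n",
                p$factor, p$contrast, p$estimate, p$df, p$t, p$p_tukey))
  }
  invisible(x)
}

#' Per-participant Welch tests of M1 vs S1 onsets
#'
#' Welch two-sample t-test of channel onsets between regions, per participant
#' and finger. Participants with 2 or fewer channels in either region are
#' excluded from testing and from the correction count; p-values are
#' Bonferroni-corrected per finger by the number of tested participants.
#'
#' @param onsets an `onset_table` with a `participant` column.
#' @param band which band to test (required if several are present).
#' @param alpha significance level after correction.
#' @param min_channels minimum channels per region to be tested (default 3,
#'   i.e. participants with <= 2 are excluded).
#' @return data.frame with one row per participant x finger: channel counts,
#'   `tested`, `t`, `df`, `p_raw`, `p_bonferroni`, `significant`.
#' @export
per_participant_tests <- function(onsets, band = NULL, alpha = 0.05, min_channels = 3L) {
  onsets <- .require_onset_cols(onsets)
  if (is.null(band)) {
    band <- unique(onsets$band)
    if (length(band) > 1) stop("several bands present; pick one via `band`")
  }
  onsets <- onsets[onsets$band == band & onsets$region %in% c("M1", "S1"), , drop = FALSE]
  out <- list()
  for (fg in sort(unique(onsets$finger))) {
    sub <- onsets[onsets$finger == fg, , drop = FALSE]
    rows <- lapply(sort(unique(sub$participant)), function(pp) {
      d <- sub[sub$participant == pp, ]
      m1 <- d$onset_s[d$region == "M1"]; s1 <- d$onset_s[d$region == "S1"]
      tested <- length(m1) >= min_channels && length(s1) >= min_channels
      if (tested) {
        tt <- stats::t.test(m1, s1, var.equal = FALSE)
        data.frame(participant = pp, finger = fg, n_M1 = length(m1), n_S1 = length(s1),
                   tested = TRUE, t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value)
      } else {
        data.frame(participant = pp, finger = fg, n_M1 = length(m1), n_S1 = length(s1),
                   tested = FALSE, t = NA_real_, df = NA_real_, p_raw = NA_real_)
      }
    })
    rows <- do.call(rbind, rows)
    m <- sum(rows$tested)
    rows$p_bonferroni <- pmin(1, rows$p_raw * m)
    out[[fg]] <- rows
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out
}

#' Percentage of M1 channels in the earliest onset quartile
#'
#' Pools all M1 and S1 onsets, takes the earliest `ceiling(n / 4)` channels
#' (ties at the quartile boundary are all included, which may enlarge the
#' set) and reports the percentage of M1 channels among them.
#'
#' @param onsets an `onset_table` (any grouping columns are ignored unless
#'   `by` is given).
#' @param by optional character vector of grouping columns (e.g.
#'   `c("participant", "finger")`); if supplied, a data.frame with one `pct`
#'   per group is returned.
#' @return numeric percentage in [0, 100], or a data.frame when `by` is used.
#' @export
earliest_quartile_pct <- function(onsets, by = NULL) {
  stopifnot(is.data.frame(onsets))
  if (!is.null(by)) {
    grp <- interaction(onsets[, by, drop = FALSE], drop = TRUE)
    parts <- split(onsets, grp)
    out <- do.call(rbind, lapply(parts, function(d) {
      cbind(unique(d[, by, drop = FALSE]), pct = earliest_quartile_pct(d))
    }))
    rownames(out) <- NULL
    return(out)
  }
  d <- onsets[onsets$region %in% c("M1", "S1"), , drop = FALSE]
  n <- nrow(d)
  if (n < 4) stop("need at least 4 channels for a quartile")
  q <- ceiling(n / 4)
  cut <- sort(d$onset_s)[q]
  sel <- d$onset_s <= cut + 1e-12          # boundary ties all included
  100 * sum(d$region[sel] == "M1") / sum(sel)
}

#' Earliest-activating channel
#'
#' @param onsets an `onset_table`.
#' @param by optional grouping columns, as in [earliest_quartile_pct()].
#' @return one-row data.frame (`channel`, `region`, `onset_s`), or one row per
#'   group when `by` is used. Ties are broken by table order with a message.
#' @export
earliest_channel <- function(onsets, by = NULL) {
  stopifnot(is.data.frame(onsets), nrow(onsets) > 0)
  if (!is.null(by)) {
    grp <- interaction(onsets[, by, drop = FALSE], drop = TRUE)
    out <- do.call(rbind, lapply(split(onsets, grp), function(d) {
      cbind(unique(d[, by, drop = FALSE]), earliest_channel(d))
    }))
    rownames(out) <- NULL
    return(out)
  }
  i <- which(onsets$onset_s == min(onsets$onset_s))
  if (length(i) > 1) {
    message("earliest_channel: tie between ", length(i),
            " channels; first by table order returned")
  }
  i <- i[1]
  data.frame(channel = onsets$channel[i], region = onsets$region[i],
             onset_s = onsets$onset_s[i], stringsAsFactors = FALSE)
}
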