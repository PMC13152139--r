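Package: ecogtiming
Title: Neural Onset Latency Analysis for Sensorimotor ECoG
Version: 0.1.0
Authors@R:
    person("ECoG Timing", "Developers", email = "ecogtiming@example.org",
           role = c("aut", "cre"))
Description: Tools to measure the relative timing of movement-related neural
    activity across sensorimotor cortex from electrocorticography (ECoG)
    recordings. The package covers the full analysis path: synthetic
    multichannel recordings with known ground-truth onsets, bad-channel
    screening and common-average referencing, amplifier-equalizing filters,
    dataglove movement-onset markers and gamma-slope trial alignment, Morlet
    wavelet band power, task-responsive channel selection with signed-r2
    maps, per-channel neural-onset detection with adaptive threshold
    optimization, and M1 versus S1 group statistics (repeated-measures
    ANOVA, per-participant Welch tests, earliest-quartile summaries).
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
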