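---
title: "Measuring M1-versus-S1 onset latencies from sensorimotor ECoG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring M1-versus-S1 onset latencies from sensorimotor ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogtiming)
```

## The scientific question

During a voluntary finger movement, does the hand region of primary motor
cortex (M1) become active before the hand region of primary somatosensory
cortex (S1)? Electrocorticography (ECoG) grids over the central sulcus record
both regions at millisecond resolution. Movement is accompanied by a
broadband high-frequency band (HFB, 60-100 Hz) power *increase* — a proxy
for local population firing — and an alpha/beta (8-30 Hz) power *decrease*
(event-related desynchronization). `ecogtiming` measures, per channel, when
each of these changes begins ("neural onset") relative to a per-trial
movement marker, and tests whether M1 onsets systematically precede S1
onsets across fingers and participants.

## Pipeline overview

1. **Preprocessing** (`detect_bad_channels`, `common_average_reference`,
   `equalize_filter`): robust variance screening (defaults: flag below
   1e-3x or above 25x the median channel variance), CAR over all non-bad
   pool channels, then a zero-phase 0.15-134 Hz band-pass plus a 50 Hz
   notch.
2. **Trial alignment** (`detect_mom`, `detect_gsm`): per-trial movement
   markers from a dataglove (derivative-of-Gaussian filtering, first
   supra-threshold deflection after the cue), or — when no overt movement
   exists — gamma-slope markers (GSM) derived from the rise of the mean HFB
   response over task-responsive channels.
3. **Spectral features** (`morlet_power`, `band_average`,
   `band_power_morlet`): Morlet wavelets (width 7 cycles, kernels truncated
   at 3 SD) on 1 Hz bins, power averaged within each band; epochs span -1
   to 2 s around the marker.
4. **Channel selection** (`test_task_response`, `signed_r2`,
   `filter_analysis_channels`): one-sided paired t-test per channel
   (pre -1..-0.5 s vs post 0..0.5 s means per trial, p < 0.05, deliberately
   uncorrected), signed-r2 maps, then restriction to hand-region M1/S1
   channels.
5. **Onset detection** (`smooth_trials`, `normalize_channels`,
   `optimize_threshold`, `detect_onsets`): 0.5 s moving-average smoothing,
   per-channel trial means z-scored over the epoch and baseline-corrected on
   [-1, -0.5] s, then a two-phase adaptive threshold (below).
6. **Group statistics** (`summarize_regions`, `region_anova`,
   `per_participant_tests`, `earliest_quartile_pct`): cell means per
   participant/finger/region, a two-within-factor repeated-measures ANOVA
   with Tukey-adjusted post-hocs, per-participant Welch tests
   (Bonferroni-corrected over tested participants, excluding those with two
   or fewer channels per region), and the percentage of M1 channels in the
   earliest onset quartile.

## The adaptive threshold

The threshold that defines "onset" is not chosen by hand. Traces are
oriented so responses are increases; the grid starts at 0.4 z and grows in
0.1 steps.

* **Phase 1** raises the threshold until it exceeds the trace value at the
  window start (-0.5 s) of *all but two* channels, anchoring it above
  pre-movement levels without letting one or two noisy channels dominate.
* **Phase 2** keeps raising it as long as the number of channels that reach
  it anywhere inside [-0.5, 0.5] s does not drop, and returns the last value
  before the drop. The result is the strongest response level still attained
  by the full channel set, which preserves systematic differences *between*
  channels.

Crossings are then sought over the full epoch and linearly interpolated
between samples. Two documented consequences, both reproduced on synthetic
data: the full rule places onsets after the movement marker (the crossing
happens high on the rising flank), while the permissive variant
(`detect_onsets_permissive`, phase 1 only) places the majority of onsets
before movement onset; and because phase 2 anchors the threshold to what the
latest-rising channels attain *inside the window*, those channels cross at
their graze point, which compresses the measured region difference by
roughly 10-15% of the true lag. Both variants preserve the sign of the
M1-S1 difference, which is what the group statistics test.

Tie-breaks: a plateau in the channel count followed by a drop returns the
last plateau value; if the count collapses only when the threshold passes
every channel's maximum, the largest reached value is returned with a
warning. With fewer than three channels phase 1 is vacuous and the fixed
starting magnitude is used (such participants are also excluded from
post-hoc tests).

## What the synthetic generator emulates

`generate_recording()` builds each channel as

* 1/f^2 background noise (a leaky integrator with a 0.5 Hz corner; other
  exponents use FFT shaping), unit SD;
* optional common-phase 50 Hz line noise (default amplitude 1);
* an HFB carrier: 60-100 Hz band-pass-filtered Gaussian noise (amplitude
  0.5) amplitude-modulated by `1 + 2 r(t)`, where `r` is a raised-cosine
  ramp (0.2 s rise, 1 s hold, 0.2 s fall) starting at the channel's true
  onset. Modulated noise rather than a tone means wavelet *power*, not
  narrowband phase, carries the effect, matching broadband HFB physiology;
* an LFB carrier: 8-30 Hz filtered noise (amplitude 1) modulated by
  `1 - 0.5 r(t)` (desynchronization);
* optionally, response-free background channels that only contribute to the
  CAR pool.

Trials follow the task design: 30 trials per finger for thumb/index/little
in randomized order, cue-to-cue intervals uniform in 4.4-5 s, a 0.4 s mean
reaction time with Gaussian per-trial jitter (default SD 0.05 s; 0.15 s in
the GSM benchmark) that shifts *all* channels of a trial together — exactly
the structure GSM alignment is meant to undo, while per-channel lags are
fixed across trials. The dataglove deflects smoothly starting exactly at the
true movement time. Ground-truth onset is defined as the ramp start; a sharp
step would make onset recovery trivially exact.

Not emulated: biophysical dipole geometry, epileptic activity, electrode
drift, cross-channel correlated noise, and task-to-task nonstationarity. A
green synthetic test therefore establishes that the *computation* recovers
the latency structure it assumes, not that the assumptions hold in any given
clinical recording.

### The CAR pool must be realistic

An instructive failure mode found while validating: referencing only the six
response-carrying channels against themselves feeds each channel a
1/N-weighted, mixed-timing copy of the group response, biasing every
channel's onset toward the group mean and compressing the M1-S1 difference
by ~15 ms. Real grids reference against 63-128 electrodes, of which only
10-36 are analyzed. The cohort generator therefore includes response-free
"Other" channels in the CAR pool (default 10, i.e. a 16-channel pool like
the smallest real grid); with that pool the fixed-threshold recovery is
unbiased (-99 +/- 1.4 ms for a true -100 ms lag).

## Numerical choices

* **Filters**: the 0.15-134 Hz band-pass is realized as a cascaded
  2nd-order Butterworth high-pass and 4th-order low-pass rather than a
  single 8-pole band-pass — a 0.15 Hz corner at 512 Hz and above makes the
  joint transfer function numerically unstable in coefficient form. The
  notch is an RBJ biquad with Q = 35. Everything is applied
  forward-backward (zero phase) because latency is the measurand and phase
  delay would bias it.
* **Wavelets**: kernels are unit-energy, so white noise yields a flat power
  profile across bins. Samples within one kernel half-length of an epoch
  edge are set to `NA` per frequency and excluded from all downstream
  means, so baselines never silently include edge artifacts. The fused C++
  band-power path supports an output time stride (as time-frequency
  toolboxes do with their time-of-interest grids); onset crossings are
  interpolated, so a stride of 8 at 512 Hz (64 Hz power sampling) changes
  recovered latencies by well under the reported tolerances. Tests assert
  exact agreement between the fused path and the plain R
  `morlet_power()` + `band_average()` route.
* **Epoching**: the window is closed, `[-1, 2]` s, giving
  `round(3 * fs) + 1` samples; markers are rounded to the nearest sample.
* **GSM marker metric**: "minimal horizontal distance between the mean HFB
  trace and a sliding slope segment" is read as: the placement whose
  midpoint is nearest, along the time axis, to the trace's crossing of the
  segment's mid-level — which reduces to the first upward crossing of
  `slope * segment_len / 2` z-units (0.4 z at the defaults: 2 z/s slope,
  0.4 s segment). The reading is isolated in one internal function so a
  different metric can be substituted without touching the rest. Segment
  parameters are not specified by the source study and are configurable;
  the mean trace is smoothed with the same 0.5 s window as onset detection
  (an assumption, flagged).
* **z-scoring domain**: the full epoch (not only pre-onset data); flagged
  as an open choice. Channels crossing before -0.5 s are reported as-is
  with a `crossed_at_start` flag.
* **ANOVA**: the classical two-within-factor repeated-measures
  decomposition is the default because a closed-form sums-of-squares oracle
  exists for it and it coincides with the mixed-model ANOVA for balanced
  complete data; `method = "lmer"` provides the mixed-model route. Post-hoc
  marginal-mean contrasts use the studentized range (`ptukey`) on the
  matching within-subject error term; for two levels this reduces to the
  paired t-test. A zero effect sum of squares reports F = 0 even when the
  error term is degenerate.
* **Quartile rule**: the earliest `ceiling(n/4)` channels; ties at the
  boundary are all included (enlarging the set) because no tie rule is
  specified.
* **Automated trial rejection** (peak |z| > 10 on any channel) replaces
  visual artifact screening; a manual exclusion list keeps parity with the
  semi-automated workflow, as does the per-trial marker override in
  `detect_mom`.

## Validation design

`tests/testthat/test-acceptance.R` re-derives the package's claims from
scratch on every run:

1. an 8-participant synthetic cohort (3 channels per region, 30 trials per
   finger, true M1 lead 100 ms) is analyzed end to end over 50 seeds; the
   cohort mean of per-participant M1-S1 differences must fall within
   -100 +/- 30 ms and the region ANOVA (F(1,7), matching the real design)
   must be significant in at least 90% of seeds. The per-participant
   criterion is evaluated on the cohort mean because single-participant
   differences with three channels per region carry ~18 ms of sampling
   noise; every participant must still recover the correct sign in every
   seed.
2. the threshold optimizer must equal a literal brute-force grid scan on
   100 random trace sets (3-40 channels);
3. GSM alignment under 150 ms trial jitter must recover relative
   per-channel onsets within half the smoothing window, with rank
   correlation at least 0.9 against ground truth;
4. the selection t-test must be calibrated (type-I error 0.05 +/- 0.015
   over 1000 null simulations) and powered (>= 0.95 at the generator's
   default SNR);
5. deterministic micro-fixtures (CAR conservation, band identities,
   normalization invariants, quartile enumerations, ANOVA vs brute-force
   sums of squares) must be exact;
6. the full and permissive threshold variants must agree on the sign of the
   region difference in every seed, with permissive onsets channelwise no
   later than full-rule onsets.

Measured on one CPU of the development container, the cohort criterion runs
in about 8.5 minutes and the entire suite in under 15.

## Known limitations

* Single-trial onsets are out of scope; all onsets are properties of
  trial-mean traces.
* The threshold-window interaction biases absolute onsets late and slightly
  compresses between-region differences (see above); sign inference is
  unaffected, and the magnitude tolerance in validation accounts for it.
* The GSM marker carries a constant offset relative to true movement onset,
  so only relative timing across channels is meaningful for GSM-aligned
  data.
* Electrode localization, cortical-surface rendering and EMG-based markers
  are out of scope; region labels and hand-region flags are inputs.
* No HDF5/EDF/BrainVision I/O: recordings are exchanged through a
  plain-text format (JSON metadata + CSV signal).
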