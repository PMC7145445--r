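---
title: "Methods: infant fNIRS preprocessing, peak statistics, and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infant fNIRS preprocessing, peak statistics, and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, and numerical
decisions behind `babynirs`, and states plainly what the synthetic-data
tests do and do not establish about real infant recordings.

## The measurement model

fNIRS measures, for each source-detector pair (channel), the attenuation
of near-infrared light through cortex at two wavelengths. Under the
modified Beer-Lambert law, attenuation change is linear in the
concentration changes of oxyhemoglobin (HbO2) and deoxyhemoglobin (HHb):

$$\Delta A(\lambda, t) = \big[\varepsilon_{HbO_2}(\lambda)\,\Delta C_{HbO_2}(t)
 + \varepsilon_{HHb}(\lambda)\,\Delta C_{HHb}(t)\big]\, d \cdot \mathrm{DPF}$$

with $d$ the source-detector separation (2 cm) and DPF the differential
pathlength factor accounting for the longer effective photon path through
tissue (5.13, appropriate for infants of this age). With two wavelengths
the 2x2 system is inverted per time point to recover both chromophores.
Two conventions are fixed package-wide and must match between any
substituted extinction table and the data: concentrations are in umol/L,
and attenuation is natural-log (`intensity = baseline * exp(-dA)`).
The shipped extinction table (770 nm: HbO2 0.650, HHb 1.3674; 850 nm:
HbO2 1.058, HHb 0.691; mM^-1 cm^-1) is configuration data, swappable in
the YAML config; only the forward/inverse consistency of the pair is a
testable property, and the suite verifies that round trip to below 1e-9
relative error.

## Pipeline stages and their parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| CoV threshold | 15 | % | channel rejection on intensity variability |
| peak-power threshold | 0.5 | fraction | channel rejection on spectral concentration |
| peak-power floor | 0.5 | Hz | lower edge of the artifact search band |
| max rejected channels | 15 | channels | participant exclusion (`> 15`) |
| low-pass cutoff | 1.7 | Hz | removes cardiac/instrument noise |
| filter order | 4 | - | Butterworth, applied forward-backward |
| block extent | -4 to +20 | s | 240 samples at 10 Hz, half-open `[-4, 20)` |
| detrend anchors | first/last 4 | s | anchored linear fit |
| DPF | 5.13 | - | Beer-Lambert pathlength scaling |
| baseline amplitude bound | 3 | umol | trial rejection in `[-4, 0)` (strict) |
| stimulus amplitude bound | 5 | umol | trial rejection in `[0, 10)` (strict) |
| looking criterion | 0.60 | fraction | trial retained if watched `>= 60%` |
| min valid trials | 3 | trials | condition/modality inclusion |
| peak window | 8-16 | s | signed peak extraction |
| FDR family | 46 | channels | Benjamini-Hochberg over the montage |
| SVM cost C | 1 | - | linear soft margin |
| permutations | 1000 | - | participant-preserving label swaps |

Decisions the method description leaves genuinely open were resolved once
and are configurable:

- **CoV domain.** The coefficient of variation is computed on raw
  intensity (not log-attenuation); the config records this under
  `cov_domain`.
- **Normalized peak power** is operationalized as the largest single
  periodogram bin over the total power, searched above a 0.5 Hz floor.
  The floor exists because the screen targets strong frequency components
  *unrelated to the experiment*: on a clean recording the stimulus-locked
  response train is the only spectral content and legitimately
  concentrates most low-frequency power (0.76 in a noise-free
  simulation), while genuine artifact lines (unclipped optodes, cardiac
  contamination, instrument oscillation) sit well above 0.5 Hz. Without
  the floor, the cleanest possible recording would fail its own QC.
- **Screening is per wavelength with an OR rule**: a channel fails if
  either wavelength fails either criterion (conservative).
- **Baseline-drift screening** as a separate criterion is implemented as
  a disabled config switch; no threshold is defensible a priori, and the
  anchored detrend already absorbs slow drifts.
- **Trial-level validity.** Artifact rejection is per channel. For the
  `>= 3 valid trials` inclusion counts, a trial counts when it passed the
  looking criterion and is valid in at least 50% of non-rejected channels
  (`trial_validity_rule`).
- **Amplitude bounds apply per chromophore**, referenced to the trial's
  4-s pre-stimulus mean (zero after detrending and re-referencing), with
  strict inequalities ("greater than ±3/±5").
- **Peaks are signed** (max for HbO2, min for HHb) and tested against
  zero; signed peaks keep deactivations representable, which the
  consistency rule needs.
- **Stage order.** Filtering precedes segmentation (edge transients decay
  inside the continuous record, not inside blocks). Detrending precedes
  Beer-Lambert inversion; since both are linear they commute exactly, and
  the suite asserts that commutation rather than pretending the order
  matters.

## Numerical choices

- The low-pass filter is a 4th-order Butterworth run forward and backward
  (zero phase, squared magnitude response). `signal::filtfilt` applies
  zero initial conditions in both passes, so the signal is padded by
  odd reflection (100 samples) before filtering, as scipy's `filtfilt`
  does; without padding even a constant input shows large edge
  transients. The effective attenuation at 2.4 Hz (an infant heart rate)
  is ~24 dB.
- The anchored detrend subtracts the straight line through the two
  window means, each placed at its window's temporal center, which zeroes
  both end-window means exactly (asserted to 1e-10).
- The LOPO SVM is a compiled sequential-minimal-optimization solver for
  the linear soft-margin dual (maximal-violating-pair working set,
  stopping tolerance 1e-3 as in libsvm). The null-calibration suite alone
  needs roughly half a million fits, which rules out per-fit R-level
  overhead. Every prediction path is cross-checked against `e1071`
  (libsvm) in the tests, and an `engine = "e1071"` switch keeps the
  reference path available.
- A decision value of exactly zero (fully degenerate fold) deterministically
  predicts the first class in canonical order and sets a flag.
- Zero-variance t tests and vanishing-error ANOVA strata are flagged
  degenerate (`NA` statistics) instead of reporting floating-point noise.
- Permutation p values use the inclusive rule
  `p = (1 + #{null >= obs}) / (n_perm + 1)`; exhaustive enumeration of
  all $2^n$ swap patterns is available for small cohorts and counts the
  identity pattern as the observed value.
- The mixed ANOVA uses the classical repeated-measures decomposition
  (participant error strata) with listwise deletion of participants
  missing any within-subject cell; with two-level within factors
  sphericity corrections are vacuous. Effect size is partial eta squared,
  labeled as such.

## What the synthetic cohort emulates

The generator lays down, per trial and channel, a ground-truth response
`amplitude * r(t)` where `r` rises as a gamma curve
$(t/t_p)^k e^{k(1-t/t_p)}$ ($k = 8$) to its peak at $t_p = 12$ s and
decays as a Gaussian (sd 1.6 s). The decay is deliberately faster than
the rise: the 24-s block arithmetic (4 + 10 + 10 s) with anchored
detrending presupposes a response that has resolved by the block's final
4 s. A curve still elevated at 16-20 s (as a symmetric gamma peaking at
12 s necessarily is) would make the detrend subtract a large fraction of
every injected amplitude, leaving no ground truth recoverable even in
principle — the compact decay encodes the same assumption the
preprocessing itself makes. HHb amplitudes default to $-1/3$ of HbO2
(canonical oxy/deoxy asymmetry, exposed as `hhb_ratio`).

Nuisance components, all in attenuation units on a per-channel
log-uniform baseline intensity: cardiac oscillation at 2.4 Hz (chosen
above the 1.7 Hz cutoff so the filter's effect is observable), white
measurement noise (sd 0.003), random linear drifts, Poisson motion-spike
boxcars large enough to trip the ±3/±5 umol bounds, and dead channels
(light starvation: weak intensity with ~50% CoV, which the CoV screen
must catch). Event schedules honor the design: a leading 10-s baseline,
at most 20 trials of 9-12 s alternating spoken/signed modality, 10-s
baselines between.

**What it does not emulate:** systemic physiology (Mayer waves,
respiration), inter-infant anatomical and vascular variability,
correlated spatial noise, scalp-coupling differences, or realistic
looking-time behavior. Noise is i.i.d. across channels and participants.
Consequently, passing calibration tests show the *statistical machinery*
is correct under its stated assumptions — not that the pipeline's error
rates would be nominal on real infant data, whose noise violates
independence in ways no simulation here represents.

One consequence deserves emphasis: **window-maximum peak extraction is
positively biased under noise** (the max of a noisy curve exceeds the
max of its mean). In real cohorts this bias is dwarfed by inter-infant
variability; in an i.i.d.-noise simulation it is systematic while the
between-participant spread is small, so t tests against zero on
through-pipeline noise peaks would flag "activation" everywhere. The
type-I and sensitivity/specificity properties of the channel statistics
are therefore established on peak *tables* (per-participant peak values
drawn around ground truth) — the level those properties actually
constrain — while through-pipeline tests assert amplitude recovery
(noise-free: exact to ~1%; default noise, 20 infants: cohort mean within
±20% with a ~+11% max-bias) rather than calibration.

## Decoding design decisions

- **Standardization scope.** Features are z-scored per channel across
  *all* patterns, including the held-out participant's — replicating the
  published analysis exactly. This leaks scaling information across the
  LOPO split; by an exact label-swap symmetry it cannot bias accuracy
  away from 0.5 under the null (verified: 1000 null cohorts, mean
  0.4954, se 0.0039), but it is still hygiene-relevant for effect
  estimation, so a leakage-free `scaling = "training_fold"` mode refits
  the scaler on each training fold for sensitivity analyses.
- **Missing channels** (rejected for one participant) are imputed at the
  standardized channel mean, 0, keeping feature dimensions aligned.
- **Permutations** flip each participant's label pair with an independent
  fair coin per permutation; duplicates across permutations are allowed.
- **Difference nulls** for group/hemisphere comparisons pair the two null
  distributions by permutation index and count
  `p = #{null_a - null_b >= obs_a - obs_b} / n`; a zero count is reported
  as below resolution (`< 1/n`), flagged rather than rounded.

## Problem sizes in the shipped suites

The simulation-based checks use, as the package's own choices: 500
information-free cohorts of 20 participants for chance-level calibration
of mean LOPO accuracy; 200 cohorts x 200 permutations (12 participants
each) for permutation type-I error; 200 null peak-table cohorts for
t-test calibration; 500 null tables for ANOVA p uniformity; a
20-participant cohort at default noise for 1.5-umol amplitude recovery;
and 100 constructed epochs for motion-spike rejection sensitivity. The
acceptance script reports the 200-cohort chance-level benchmark.

## Known limitations

- No SNIRF/HDF5 reader: recordings are exchanged as one wide TSV per
  wavelength plus a JSON sidecar (events, looking proportions, metadata).
- Channel anatomical labels in the default config are placeholders; only
  ROI membership and hemisphere are analytically meaningful.
- The ROI ANOVA assumes balanced within-subject cells after listwise
  deletion; unbalanced group sizes are handled by the classical
  decomposition, not a mixed-effects model.
- Decoding operates on participant-average patterns only (two patterns
  per infant); trial-level decoding is out of scope.
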