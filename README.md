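# babynirs

Analysis of infant functional near-infrared spectroscopy (fNIRS) language
experiments, from raw dual-wavelength optical intensity to channel-wise
activation maps, region-of-interest (ROI) ANOVAs, and multivariate decoding
of language conditions. It is written for developmental-neuroimaging
researchers who run block-design fNIRS studies with infants (here: spoken
vs. signed language in monolingual, unimodal-bilingual, and
bimodal-bilingual infants) and want every analysis stage reproducible and
testable without access to the original recordings.

## What it computes

**Channel quality control.** Each of the 46 channels (23 per hemisphere,
2 cm source-detector separation, 770/850 nm, 10 Hz) is screened per
wavelength on the session intensity: rejected if the coefficient of
variation `100 * sd/mean` exceeds 15% or if one spectral bin above 0.5 Hz
holds more than 50% of the band's periodogram power. An infant with more
than 15 rejected channels is excluded.

**Hemodynamic preprocessing.** Intensity is low-pass filtered (zero-phase
Butterworth, 1.7 Hz cutoff), converted to attenuation change, segmented
into 24-s blocks (4-s pre-stimulus baseline + 10-s stimulus + 10-s
post-baseline), detrended by the line through the first- and last-4-s
window means, and converted to oxy-/deoxyhemoglobin concentration changes
(micromolar) by inverting the modified Beer-Lambert law

```
dA(lambda) = [ eps_HbO2(lambda) * dHbO2 + eps_HHb(lambda) * dHHb ] * d * DPF
```

with source-detector separation `d = 2` cm and differential pathlength
factor `DPF = 5.13`. Trials are dropped when the infant watched less than
60% of the stimulus, and per channel when concentration changes exceed
±3 umol in the baseline or ±5 umol during the stimulus. Condition averages
require at least 3 valid trials, with paired spoken (and signed) conditions
excluded together.

**Statistics.** Peak amplitude variation from baseline is extracted in the
8-16 s post-onset window (signed: maximum for HbO2, minimum for HHb);
channel-wise two-tailed t tests are corrected by Benjamini-Hochberg FDR
over the 46 channels, and channels where both chromophores move in the
same direction are labeled inconsistent with a hemodynamic response. ROI
mean peaks feed a 2 (modality) x 2 (hemisphere) x 3 (group) mixed ANOVA
with partial eta squared.

**Decoding.** Per-participant condition patterns (HbO2 peaks over 46, or
23 per-hemisphere, channels; z-scored within channel across infants) are
classified with a linear soft-margin SVM (C = 1) under
leave-one-participant-out cross-validation: n participants give 2n
classification trials. Inference uses participant-preserving permutations
(each participant's two labels kept or swapped with probability 1/2) with
the inclusive p-value rule, so 1,000 permutations give a p floor of
1/1001; group and hemisphere contrasts subtract paired null distributions.

A synthetic cohort generator produces raw recordings with known
ground-truth responses (gamma-rise/Gaussian-decay curves peaking ~12 s
post-onset), cardiac oscillation, drifts, motion spikes, and dead
channels, so every stage above is testable end to end.

## Worked example

```r
library(babynirs)
cfg <- default_config()
run <- run_pipeline(cfg, participants = make_participants(4, 4, 4),
                    scenario = "modality_contrast", seed = 42,
                    n_permutations = 200)
summarize_run(run)
```

The `modality_contrast` scenario injects bilateral frontal/temporal
responses to spoken language and right-posterior-temporal responses to
signed language. The report (abridged) shows the generator's structure
recovered by the pipeline:

```
== ROI ANOVA ==
  posterior_temporal:
    modality                     F(1,9)=243.06 p=0.0000 pes=0.964
    hemisphere                   F(1,9)=91.37  p=0.0000 pes=0.910
    modality x hemisphere        F(1,9)=195.20 p=0.0000 pes=0.956

== decoding (spoken vs signed) ==
  all          all    n=12 acc=1.000 p=0.0050
  all          left   n=12 acc=1.000 p=0.0050
  monolingual  all    n= 4 acc=1.000 p=0.1144
```

The posterior temporal ROI shows the injected modality-by-hemisphere
interaction (signed responses right-lateralized); whole-cohort decoding of
spoken vs. signed patterns is perfect with the permutation p at its floor
for 200 permutations (1/201 ≈ 0.005), while 4-infant within-group analyses
are honestly underpowered (p ≥ 0.1).

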