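montage:
  separation_cm: 2.0
  wavelengths_nm:
  - 770.0
  - 850.0
  sampling_rate_hz: 10.0
  channels:
  - id: 1
    source: 1
    detector: 1
    hemisphere: left
    label: inferior_frontal_L
  - id: 2
    source: 1
    detector: 1
    hemisphere: left
    label: inferior_frontal_L
  - id: 3
    source: 1
    detector: 1
    hemisphere: left
    label: inferior_frontal_L
  - id: 4
    source: 2
    detector: 2
    hemisphere: left
    label: inferior_frontal_L
  - id: 5
    source: 2
    detector: 2
    hemisphere: left
    label: inferior_frontal_L
  - id: 6
    source: 2
    detector: 2
    hemisphere: left
    label: inferior_frontal_L
  - id: 7
    source: 3
    detector: 3
    hemisphere: left
    label: inferior_frontal_L
  - id: 8
    source: 3
    detector: 3
    hemisphere: left
    label: inferior_frontal_L
  - id: 9
    source: 3
    detector: 3
    hemisphere: left
    label: anterior_temporal_L
  - id: 10
    source: 4
    detector: 4
    hemisphere: left
    label: anterior_temporal_L
  - id: 11
    source: 4
    detector: 4
    hemisphere: left
    label: anterior_temporal_L
  - id: 12
    source: 4
    detector: 4
    hemisphere: left
    label: anterior_temporal_L
  - id: 13
    source: 5
    detector: 5
    hemisphere: left
    label: anterior_temporal_L
  - id: 14
    source: 5
    detector: 5
    hemisphere: left
    label: posterior_temporal_L
  - id: 15
    source: 5
    detector: 5
    hemisphere: left
    label: posterior_temporal_L
  - id: 16
    source: 6
    detector: 6
    hemisphere: left
    label: posterior_temporal_L
  - id: 17
    source: 6
    detector: 6
    hemisphere: left
    label: posterior_temporal_L
  - id: 18
    source: 6
    detector: 6
    hemisphere: left
    label: posterior_temporal_L
  - id: 19
    source: 7
    detector: 7
    hemisphere: left
    label: posterior_temporal_L
  - id: 20
    source: 7
    detector: 7
    hemisphere: left
    label: temporoparietal_L
  - id: 21
    source: 7
    detector: 7
    hemisphere: left
    label: temporoparietal_L
  - id: 22
    source: 8
    detector: 8
    hemisphere: left
    label: temporoparietal_L
  - id: 23
    source: 8
    detector: 8
    hemisphere: left
    label: temporoparietal_L
  - id: 24
    source: 9
    detector: 9
    hemisphere: right
    label: inferior_frontal_R
  - id: 25
    source: 9
    detector: 9
    hemisphere: right
    label: inferior_frontal_R
  - id: 26
    source: 9
    detector: 9
    hemisphere: right
    label: inferior_frontal_R
  - id: 27
    source: 10
    detector: 10
    hemisphere: right
    label: inferior_frontal_R
  - id: 28
    source: 10
    detector: 10
    hemisphere: right
    label: inferior_frontal_R
  - id: 29
    source: 10
    detector: 10
    hemisphere: right
    label: inferior_frontal_R
  - id: 30
    source: 11
    detector: 11
    hemisphere: right
    label: inferior_frontal_R
  - id: 31
    source: 11
    detector: 11
    hemisphere: right
    label: inferior_frontal_R
  - id: 32
    source: 11
    detector: 11
    hemisphere: right
    label: anterior_temporal_R
  - id: 33
    source: 12
    detector: 12
    hemisphere: right
    label: anterior_temporal_R
  - id: 34
    source: 12
    detector: 12
    hemisphere: right
    label: anterior_temporal_R
  - id: 35
    source: 12
    detector: 12
    hemisphere: right
    label: anterior_temporal_R
  - id: 36
    source: 13
    detector: 13
    hemisphere: right
    label: anterior_temporal_R
  - id: 37
    source: 13
    detector: 13
    hemisphere: right
    label: posterior_temporal_R
  - id: 38
    source: 13
    detector: 13
    hemisphere: right
    label: posterior_temporal_R
  - id: 39
    source: 14
    detector: 14
    hemisphere: right
    label: posterior_temporal_R
  - id: 40
    source: 14
    detector: 14
    hemisphere: right
    label: posterior_temporal_R
  - id: 41
    source: 14
    detector: 14
    hemisphere: right
    label: posterior_temporal_R
  - id: 42
    source: 15
    detector: 15
    hemisphere: right
    label: posterior_temporal_R
  - id: 43
    source: 15
    detector: 15
    hemisphere: right
    label: temporoparietal_R
  - id: 44
    source: 15
    detector: 15
    hemisphere: right
    label: temporoparietal_R
  - id: 45
    source: 16
    detector: 16
    hemisphere: right
    label: temporoparietal_R
  - id: 46
    source: 16
    detector: 16
    hemisphere: right
    label: temporoparietal_R
rois:
  inferior_frontal:
  - 3
  - 4
  - 6
  - 7
  - 26
  - 27
  - 29
  - 30
  posterior_temporal:
  - 15
  - 16
  - 18
  - 19
  - 38
  - 39
  - 41
  - 42
design:
  conditions:
  - English
  - French
  - BSL
  - LSFB
  modality_map:
    English: spoken
    French: spoken
    BSL: signed
    LSFB: signed
  familiarity_map:
    monolingual:
      English: familiar
      French: unfamiliar
      BSL: n/a
      LSFB: n/a
    unimodal_bilingual:
      English: familiar
      French: unfamiliar
      BSL: n/a
      LSFB: n/a
    bimodal_bilingual:
      English: familiar
      French: unfamiliar
      BSL: familiar
      LSFB: unfamiliar
  baseline_duration_s: 10.0
  stimulus_duration_range_s:
  - 9.0
  - 12.0
  max_experimental_trials: 20.0
qc:
  cov_threshold_percent: 15.0
  power_threshold: 0.5
  max_rejected_channels: 15.0
  cov_domain: intensity
  drift_screening: no
preprocess:
  lowpass_cutoff_hz: 1.7
  filter_order: 4.0
  dpf: 5.13
  epoch_pre_s: 4.0
  epoch_post_s: 20.0
  baseline_limit_umol: 3.0
  stimulus_limit_umol: 5.0
  looking_threshold: 0.6
  min_valid_trials: 3.0
  trial_validity_rule: 0.5
  extinction:
    wl770:
      hbo2: 0.65
      hhb: 1.3674
    wl850:
      hbo2: 1.058
      hhb: 0.691
stats:
  peak_window_s:
  - 8.0
  - 16.0
  fdr_channels: 46.0
  alpha: 0.05
mvpa:
  cost: 1.0
  n_permutations: 1000.0
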