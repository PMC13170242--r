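# Example configuration for run_pipeline(). Unset keys fall back to
# default_pipeline_config(); class_counts replaces the default cohort
# wholesale.
seed: 1
cohort:
  class_counts:
    healthy: 4
    hemi_left: 4
    pd_ar: 4
  duration_s: 90
preprocess:
  cutoff_hz: 0.15
  window_len: 300
  overlap: 0.5
train:
  enabled: true
  max_epochs: 10
  n_folds: 3
  ablation: false
  n_augment: 1
energy:
  enabled: true
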