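# dualgait

Analysis toolkit for a self-powered, dual-mode wearable gait system: a
triboelectric plantar-pressure insole (which doubles as an energy
harvester) paired with three stretchable polymer optical strain sensors on
lower-limb muscles. The package is aimed at researchers in wearable
biosignal analysis and digital-health methods who want to study this class
of system — its optical transduction model, its signal-processing and
classification pipeline, and its energy budget — on fully synthetic,
reproducible data.

It provides:

* **Optical strain transduction** — an effective Beer–Lambert model of a
  stretchable polymer waveguide. Transmitted intensity follows
  `I(ε) = I₀ η₁ η₂ exp(−(α₀ + k_s ε) L)`, so `ln I` falls linearly in strain
  with slope `−k_s L` (a quadratic log extension is available for the
  high-strain regime). Calibration fitting reports sensitivity (mV/% strain),
  linearity R², and the maximum hysteresis error
  `H% = max_ε |V_load(ε) − V_unload(ε)| / V_FS × 100`,
  with `V_FS` the full-scale loading span.
* **A synthetic gait cohort generator** — seeded 4-channel recordings
  (plantar pressure + gastrocnemius / vastus medialis / biceps femoris
  strain, 10 Hz) with per-class archetypes: healthy, left/right hemiplegic
  asymmetry, tremor-dominant / akinetic-rigid / freezing-of-gait
  Parkinsonian subtypes; plus a staircase calibration-rig simulator.
* **Preprocessing** — mean subtraction and fourth-order zero-phase
  Butterworth high-pass baseline correction, median/IQR robust
  normalization, fixed-length overlapping windowing, and training-time
  augmentation (circular shift, noise, amplitude scaling) that inherits
  subject identity.
* **Gait feature statistics** — step detection, step frequency,
  step-interval CV, alternate-cycle symmetry index, per-channel RMS,
  Welch-based median power frequency, per-cycle peak-to-peak amplitude.
* **A dual-branch CNN-LSTM classifier** — a two-conv-block
  plantar branch and a three-conv-layer strain branch, concatenated along
  channels and fed to an LSTM with a softmax head; trained with Adam,
  learning-rate decay, dropout, weight decay and early stopping, under
  strict subject-wise grouped cross-validation with modality ablation
  (plantar only / strain only / fused). The network engine is implemented
  in base R and verified against finite-difference gradients.
* **An energy and telemetry budget** — exact duty-cycle arithmetic for an
  acquire–upload–sleep schedule, per-step harvest accounting, net surplus,
  and serial-link throughput.

## Worked example

```r
library(dualgait)

# Energy and telemetry budget of the default duty cycle
energy_report()
#> <energy_report>
#>   cycle consumption : 424.64 mJ
#>   harvest per step  : 0.7056 mJ
#>   harvest (1000 steps): 705.60 mJ
#>   net surplus       : 280.96 mJ (sustainable)
#>   link throughput   : 6.70 kbps
```

A 10-minute acquire–upload–sleep cycle at 3.2 V consumes 424.64 mJ; each
foot strike harvests 0.7056 mJ (3.92 mW × 0.25 s × 72% conversion), so
1,000 steps yield 705.6 mJ and a positive surplus — the system powers
itself during ordinary walking. The 67-byte, 10 Hz telemetry frames need
6.7 kbps on an 8N1 serial link.

```r
# Simulated staircase calibration with sensor lag and noise
curve <- simulate_calibration_run(
  transduction_params(I0 = 2, eta1 = 0.9, eta2 = 0.9,
                      alpha0 = 0.1, k_s = 0.8, L = 2.5),
  noise_sigma_mV = 3, lag_tau_s = 0.4, seed = 7)
fit_calibration(curve)
#> <calibration_fit>
#>   sensitivity: 10.53 mV/%
#>   R^2: 0.9331   order: 1
#>   hysteresis: 3.42% at 10% strain
```

The first-order sensor lag opens a loading/unloading gap whose maximum,
normalized by the full-scale span, is the hysteresis error (largest at low
strain, as for viscoelastic sensors).

```r
# A small synthetic cohort and its gait feature table
cohort <- make_cohort(cohort_spec(
  class_counts = c(healthy = 3, hemi_left = 3, pd_ar = 3),
  duration_s = 90, master_seed = 1))
feature_table(cohort)[, c("class_label", "rms_gastro", "step_frequency",
                          "step_interval_cv", "symmetry_index")]
#>   class_label rms_gastro step_frequency step_interval_cv symmetry_index
#> 1     healthy      0.351          0.899             5.09          0.995
#> 4   hemi_left      0.279          0.692            30.54          0.569
#> 7       pd_ar      0.181          0.751            11.34          0.964
#> ...
```

Healthy subjects walk near 0.9 Hz with ~5% interval variability and
symmetry near 1; hemiplegic archetypes show marked alternate-cycle
asymmetry (symmetry ≈ 0.55) and elevated variability; akinetic-rigid
archetypes show strongly reduced strain RMS. Classifier training runs
through `grouped_folds()`, `build_and_train()`, `evaluate_folds()` and
`modality_ablation()`, or end-to-end via `run_pipeline()`.

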