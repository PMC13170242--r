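---
title: "Models and methods behind dualgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualgait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualgait)
```

`dualgait` models the computational side of a self-powered dual-mode
wearable gait system: a contact–separation triboelectric insole that senses
plantar loading (and harvests the energy of each foot strike), plus three
stretchable polymer optical strain sensors over lower-limb muscles. This
vignette explains the models, the defaults, and the design choices, in the
package's own terms.

## Optical strain transduction

The strain sensor is a soft polymer waveguide between two plastic optical
fiber terminals. Transmitted intensity is modelled with an effective
Beer–Lambert law:

$$I(\varepsilon) = I_0\,\eta_1\,\eta_2\,
  \exp\!\big(-(\alpha_0 + k_s\,\varepsilon)\,L\big),$$

where $I_0$ is the injected optical power, $\eta_1,\eta_2$ the coupling
efficiencies at the two fiber interfaces, $\alpha_0$ (per mm) the intrinsic
loss, $k_s$ (per mm per unit strain) the strain extinction coefficient, and
$L$ (mm) the effective waveguide length. The assumptions are: strain is
approximately uniform along the waveguide, the couplings are only weakly
strain-dependent inside the operating window, and $L$ is treated as a fixed
effective length. Under these, $\ln I$ is linear in strain with slope
$-k_s L$, which is what `fit_calibration(domain = "log")` recovers. At
higher strains coupling mismatch and nonlinear scattering bend the log-line;
`forward_intensity(order = 2)` provides the quadratic extension
$\ln I = C - a_1\varepsilon - a_2\varepsilon^2$. Strain is stored internally
as a fraction; all I/O and reports use percent strain.

Calibration quality is summarised by three numbers:

* **Sensitivity** — the absolute slope of the replicate-mean loading branch
  in the voltage domain (mV per % strain). The demodulator maps intensity to
  millivolts affinely, so the physically meaningful $k_sL$ is recovered by a
  separate log-domain fit rather than by rescaling the voltage slope.
* **Linearity** — the ordinary $R^2$ of the same fit. On a zero-variance
  response the fit is flagged degenerate and $R^2$ is reported as 0 rather
  than raising an error.
* **Maximum hysteresis error** —
  $H\% = \max_\varepsilon |V_\mathrm{load}(\varepsilon) -
  V_\mathrm{unload}(\varepsilon)| / V_\mathrm{FS} \times 100$ with
  $V_\mathrm{FS} = |V_\mathrm{load}(\varepsilon_{max}) -
  V_\mathrm{load}(\varepsilon_{min})|$.
  Replicates are averaged pointwise *before* the scan, and ties in the
  maximum gap break toward the lowest strain. A zero full-scale span is
  reported as an explicit error.

The calibration-rig simulator sweeps the forward model up and then down a
0–100% staircase in 10% steps (three replicates by default) and applies a
first-order lag with time constant `lag_tau_s` at each dwell. The lag is the
sole hysteresis mechanism in the simulator — a deliberate simplification of
viscoelastic path dependence — and gives two useful limits: zero lag and
zero noise collapse both branches exactly, and the simulated $H\%$ grows
monotonically with the time constant.

## The synthetic cohort generator

The generator stands in for a clinical cohort; its archetypes are
*phenomenological signal models*, not biomechanical simulations, and no
claim of clinical realism is made. Defaults (60 subjects: 15 healthy, 15
left and 15 right hemiplegia, 15 Parkinsonian split evenly over the
tremor-dominant, akinetic-rigid and postural-instability/gait-difficulty
subtypes; 10 Hz sampling) mirror the kind of study the pipeline targets.

Each recording is built in three layers:

1. **Step times.** Gaussian intervals around the archetype cadence
   (`step_frequency_hz`, `step_interval_cv`). Hemiplegic archetypes split
   alternate cycle durations so the odd/even ratio equals `asymmetry_ratio`
   while preserving mean cadence; the same ratio attenuates alternate strain
   bumps. Encoding the affected side in the alternate-step parity is a
   modelling proxy — only one shoe is instrumented — but it makes both the
   temporal and the amplitude face of hemiparetic asymmetry visible to the
   downstream symmetry index, which is why the ratio acts on durations as
   well as amplitudes. The PIGD archetype deletes steps inside
   Poisson-placed freezing episodes (default 2 per minute, 5 s each).
2. **Waveforms.** The plantar channel carries one biphasic pulse per step
   (difference of two 0.08 s Gaussians, positive lobe then negative lobe,
   reflecting contact–separation polarity; pulse amplitude versus contact
   force follows a saturating logarithmic curve anchored at 500 relative
   units at 1 N and 1150 at 40 N). Each strain channel carries one smooth
   Gaussian bump per gait cycle at a channel-specific phase offset.
   Tremor-dominant archetypes add a sinusoidal overlay on the strain
   channels at 3.5 Hz — deliberately below the clinical 4–6 Hz band because
   the 10 Hz sampling rate puts 5 Hz at Nyquist; this is a representability
   compromise, not a clinical claim.
3. **Nuisance.** Additive Gaussian noise and random-walk baseline drift per
   channel.

Per-subject seeds are hashed deterministically from the master seed, so a
cohort is bit-reproducible and subjects are mutually independent. What the
generator does **not** emulate: sensor placement variability, inter-session
drift, cross-subject waveform morphology differences beyond the archetype
parameters, co-articulation between muscles, or label noise. Passing tests
on this cohort therefore demonstrates pipeline correctness and
discriminability under controlled conditions — not clinical performance.

## Preprocessing

The three strain channels are mean-subtracted and high-pass filtered with a
fourth-order Butterworth applied forward and backward (zero phase); the
plantar channel, whose information is in broadband spikes, gets mean
subtraction only. The cutoff default of 0.15 Hz sits below the slowest
plausible stepping (~0.5 Hz) yet above the drift band; it is configurable.
All four channels are then normalized per recording and channel to median 0
/ IQR 1, with a floor guard of 1e-6 on the IQR so constant channels come
out all-zero (and flagged) instead of dividing by zero.

Windows are 300 samples (30 s at 10 Hz) with 50% overlap by default;
stride is `round(window_len × (1 − overlap))` and the window count is
`floor((N − window_len)/stride) + 1`. Augmentation (training only) applies
an integer circular shift uniform in ±5 samples, Gaussian noise
(σ = 0.02 in robust units), and an amplitude scale uniform in [0.9, 1.1];
augmented windows inherit their source subject and are marked in a lineage
field so grouped splits remain valid.

One deliberate split of responsibilities: **robust normalization is
classifier preprocessing, not feature preprocessing.** Median/IQR scaling
maps every channel to the same scale, which is exactly what a
cross-participant classifier wants — and exactly what a clinical amplitude
feature does not: on the default cohort, normalization erases (and can even
invert) the reduced-RMS signature of akinetic-rigid gait. Gait features are
therefore computed on baseline-corrected, *unnormalized* signals, in sensor
units.

## Gait features

Step detection finds local maxima on the plantar channel whose topographic
prominence exceeds `prominence_factor` (default 0.5) times a robust
amplitude scale, thinned to a minimum separation of 0.3 s (higher peaks
win). The robust scale is the 99th-percentile height above the median
rather than the MAD: a spike train with a low duty cycle has a MAD that
reflects only baseline noise, which would let noise peaks through.

From the step times: step frequency = 1/mean interval; interval
CV = 100·SD/mean; the symmetry index compares mean durations of alternate
(odd/even) cycles as min/max — a left/right proxy given a single
instrumented side. Median power frequency uses a Welch estimator (Hann
window, 128-sample segments, 50% overlap, DC bin excluded) with linear
interpolation of the cumulative-power crossing; the estimator details are
package choices. Peak-to-peak amplitude is the mean per-cycle max − min.

## The dual-branch CNN-LSTM

The plantar branch applies two blocks of convolution (kernel 5) →
batch normalization → ReLU → max-pool 2, with 16 then 32 filters. The
strain branch applies three convolutions (16, 32, 64 filters) followed by a
stride-4 max-pool that aligns its temporal length with the plantar branch.
The branch outputs are concatenated along the channel axis (truncated to
the common temporal length), passed through an LSTM (64 hidden units), and
the final hidden state goes through dropout (0.3) to a softmax layer.
Training uses Adam (learning rate 1e-3, halved every 20 epochs), weight
decay 1e-4 on weight matrices, mini-batches of 32, up to 100 epochs with
patience 10. Default class scheme is the six cohort groups; any label set
works (two-, three- or four-class cohorts in the tests).

The engine is written in base R on BLAS matrix products; every layer has an
explicit forward/backward pair and the test suite checks analytic gradients
against central finite differences in all three modality architectures.
Two numerical details worth noting: batches of size 1 are skipped (batch
normalization is undefined there), and conv biases feeding a batch-norm
layer have a true gradient of ~0 (the normalization absorbs constant
shifts), so the gradient test compares errors against the global gradient
scale rather than per-parameter magnitudes.

Generalization is assessed with subject-wise grouped cross-validation:
subjects are stratified by class, shuffled with a seeded RNG and dealt
round-robin into folds (the plan is invariant to input order), giving
≈80%/20% train/test subjects per fold at the default of 5 folds. One
subject per class is held out of each training fold as an inner validation
set for early stopping, so the test fold is never touched during training.
Leakage is checked programmatically — train and test subject sets must be
disjoint in every fold, and augmented windows follow their source subject —
and evaluation uses original (never augmented) windows of held-out subjects
only.

Two properties of the evaluation design deserve a note:

* **Permutation null.** A naive check "permute subject labels, expect
  chance accuracy" is biased *below* chance when class totals are exactly
  balanced and the classifier's predictions are constant within latent
  feature groups: the test labels of a group are then anti-correlated with
  the training majority (a finite-population effect). The package's null
  check therefore permutes subject labels on a cohort whose archetypes are
  identical across nominal classes, where held-out accuracy concentrates
  near chance as intended.
* **Modality ablation.** The complementary-information cohort places one
  binary factor on the plantar channel (spike amplitude, which survives
  robust normalization because sparse spikes are scaled by the noise IQR)
  and an independent binary factor on the strain channels (a tremor
  overlay, a spectral cue). Each single modality can separate at most two
  of the four classes; only the fusion can separate all four.

## Energy and telemetry budget

Cycle energy is $\sum_i V_i I_i t_i$ in millijoules (V × mA × s); the
default scenario is 480 s acquisition at 0.2 mA, 20 s upload at 1.8 mA and
100 s sleep at 0.007 mA on a 3.2 V rail. Per-step harvest is effective
power × contact duration × conversion efficiency (3.92 mW × 0.25 s × 0.72 =
0.7056 mJ). The sustainability verdict is simply surplus ≥ 0. Link
throughput uses 10 wire bits per byte by default — start + 8 data + stop of
an 8N1 UART — which is the framing that connects a 67-byte, 10 Hz stream to
6.7 kbps. Internal arithmetic is unrounded; printing uses two decimals.

## Rehabilitation comparison

`rehab_compare()` performs per-metric two-tailed paired t-tests on subjects
present in both tables, reporting the mean difference (post − pre), 95%
confidence interval and p-value, with significance at 0.05. Metrics are
reported without multiplicity correction by default (an optional Holm
adjustment is available). Identical tables produce zero differences with
degenerate CIs and an `NA` p-value rather than an error.

## Problem sizes and tolerances in the test suite

The suite exercises the full pipeline at desk scale: training checks use
60-subject two-class cohorts with 60 s recordings (three 300-sample windows
per subject) and 5-fold grouped CV, and the ablation uses a 20-subject
four-class factorial cohort with a reduced network (4/8 conv filters, LSTM
hidden 8) — sizes chosen so the whole suite runs in a few minutes while
still training real networks. Monte-Carlo checks use 100–1000 seeded
replicates; exact arithmetic (energy, window-count formulas, hysteresis scan)
is asserted to machine precision; estimator recoveries are asserted to
their sampling error (e.g. interval CV within ±2 points at ≥100 steps,
noisy $k_sL$ within 3 standard errors).

## Known limitations

* Archetypes are phenomenological; none of the class-conditional
  parameters are clinically calibrated, so classifier accuracies on
  synthetic cohorts say nothing about clinical accuracy.
* The symmetry index uses alternate-cycle durations from a single
  instrumented side; true left/right asymmetry needs bilateral sensing.
* The sensor lag model generates rate-independent, single-time-constant
  hysteresis only.
* The network engine is CPU-bound pure R; it is meant for desk-scale
  experiments, not large-scale training.
* Fixed 10 Hz sampling; no resampling across devices.
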