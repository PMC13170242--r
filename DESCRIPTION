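Package: dualgait
Title: Dual-Mode Wearable Gait Sensing: Calibration, Simulation, Features,
    and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for a self-powered dual-mode wearable gait
    system combining a triboelectric plantar-pressure insole with stretchable
    optical muscle-strain sensors. Provides an effective Beer-Lambert model of
    optical strain transduction with calibration fitting and hysteresis
    metrics; a seeded synthetic gait-cohort generator with per-class
    archetypes (healthy, hemiplegic, Parkinsonian subtypes); signal
    preprocessing (zero-phase Butterworth baseline removal, robust
    median/IQR normalization, overlapping windowing, augmentation); gait
    feature statistics (RMS, median power frequency, cycle variability,
    symmetry); a dual-branch CNN-LSTM classifier evaluated under subject-wise
    grouped cross-validation with modality ablation; and an exact duty-cycle
    energy and telemetry budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
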