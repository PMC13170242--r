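# Shared fixtures: small cohorts and configs reused across test files.

# Two archetypes differing only in overall amplitude (strongly separable).
two_class_archetypes <- function(amp_a = 1, amp_b = 0.25, noise = 0.05) {
  list(
    classA = archetype_params("classA", amplitude_scale = amp_a,
                              noise_sigma = noise),
    classB = archetype_params("classB", amplitude_scale = amp_b,
                              noise_sigma = noise))
}

two_class_cohort <- function(n_per_class = 10, duration_s = 60, seed = 5,
                             amp_a = 1, amp_b = 0.25, noise = 0.05) {
  make_cohort(cohort_spec(
    class_counts = c(classA = n_per_class, classB = n_per_class),
    duration_s = duration_s, master_seed = seed,
    archetypes = two_class_archetypes(amp_a, amp_b, noise)))
}

# Factorial 4-class cohort where the plantar channel carries one binary
# factor and the strain channels the other: each single modality can at best
# separate two groups of two classes, the fusion can separate all four.
complementary_cohort <- function(n_per_class = 4, duration_s = 60, seed = 5) {
  arch <- function(lbl, p, s)
    archetype_params(lbl, amplitude_scale = c(p, s, s, s),
                     noise_sigma = 0.05)
  make_cohort(cohort_spec(
    class_counts = c(c_pp = n_per_class, c_pl = n_per_class,
                     c_lp = n_per_class, c_ll = n_per_class),
    duration_s = duration_s, master_seed = seed,
    archetypes = list(c_pp = arch("c_pp", 1, 1), c_pl = arch("c_pl", 1, 0.25),
                      c_lp = arch("c_lp", 0.25, 1),
                      c_ll = arch("c_ll", 0.25, 0.25))))
}

# Small network configuration for fast unit tests (not the default model).
tiny_model_config <- function(max_epochs = 4, early_stop_patience = 3, ...) {
  model_config(plantar_filters = c(4, 8), strain_filters = c(4, 8, 8),
               lstm_hidden = 8, max_epochs = max_epochs,
               early_stop_patience = early_stop_patience, ...)
}

# Noiseless calibration curve with an exact linear voltage response.
linear_curve <- function(slope = 12.25, intercept = 0,
                         grid = seq(0, 100, by = 10), gap = 0) {
  v <- intercept + slope * grid
  un <- v
  if (gap != 0) un[2] <- un[2] + gap
  calibration_curve(grid, v, un)
}
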