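test_that("steps are detected exactly on noiseless recordings", {
  a <- archetype_params("x", noise_sigma = 0, drift_sigma = 0)
  r <- simulate_recording(a, 60, "S", 7)
  st <- detect_steps(r$channels[, 1] - mean(r$channels[, 1]), r$sample_rate)
  expect_equal(length(st), length(r$true_step_times))
  expect_lt(max(abs(st - r$true_step_times)), 0.1)  # within one sample
  # flat input yields an empty result, not an error
  expect_length(detect_steps(rep(0, 100), 10), 0)
  expect_length(detect_steps(numeric(0), 10), 0)
})

test_that("step counts stay within 2% of truth under noise", {
  a <- archetype_params("x", noise_sigma = 0.1)
  errs <- vapply(1:20, function(seed) {
    r <- simulate_recording(a, 120, "S", seed)
    pp <- preprocess_recording(r)
    st <- detect_steps(pp$channels[, 1], r$sample_rate)
    step_count_error(length(st), length(r$true_step_times))
  }, numeric(1))
  expect_lt(mean(errs), 2)
})

test_that("freezing episodes propagate into long inter-step intervals", {
  a <- archetype_params("pd_pigd", freeze_rate = 4, freeze_duration_s = 5,
                        noise_sigma = 0.02)
  r <- simulate_recording(a, 120, "S", 21)
  expect_gte(max(diff(r$true_step_times)), 5)
  pp <- preprocess_recording(r)
  st <- detect_steps(pp$channels[, 1], r$sample_rate)
  expect_gte(max(diff(st)), 5)
})

test_that("interval statistics match closed forms on constructed gaits", {
  # perfectly periodic
  iv <- interval_stats(seq(0, 20, by = 1))
  expect_equal(iv$step_frequency, 1)
  expect_equal(iv$step_interval_cv, 0)
  expect_equal(iv$symmetry_index, 1)
  # alternating 0.8 / 1.2 s intervals
  st <- cumsum(c(0, rep(c(0.8, 1.2), 10)))
  expect_equal(interval_stats(st)$symmetry_index, 0.8 / 1.2,
               tolerance = 1e-9)
  # too few steps flagged as NA
  few <- interval_stats(c(0, 1))
  expect_true(is.na(few$step_interval_cv))
  expect_true(is.na(few$symmetry_index))
  expect_equal(few$step_frequency, 1)
  expect_error(interval_stats(c(0, 1, 0.5)), "increasing")
})

test_that("interval CV recovered from the generator within 2 points", {
  a <- archetype_params("x", step_frequency_hz = 1, step_interval_cv = 12.5,
                        noise_sigma = 0.02)
  r <- simulate_recording(a, 250, "S", 13)
  pp <- preprocess_recording(r)
  st <- detect_steps(pp$channels[, 1], r$sample_rate)
  expect_gte(length(st), 200)
  expect_lt(abs(interval_stats(st)$step_interval_cv - 12.5), 2)
})

test_that("rms matches closed forms", {
  expect_equal(rms(rep(-3, 10)), 3)
  t <- seq(0, 10 - 0.01, by = 0.01)           # integer number of periods
  expect_equal(rms(2.5 * sin(2 * pi * t)), 2.5 / sqrt(2), tolerance = 1e-6)
  expect_error(rms(numeric(0)), "empty")
})

test_that("median power frequency locates spectral mass", {
  fs <- 10
  t <- seq(0, 120, by = 1 / fs)
  # single line at 1.5 Hz: MPF within one bin width
  mpf1 <- median_power_frequency(sin(2 * pi * 1.5 * t), fs)
  expect_lt(abs(mpf1 - 1.5), fs / 128)
  # white noise: MPF near half Nyquist
  mpfs <- vapply(1:20, function(s) {
    set.seed(s); median_power_frequency(rnorm(1200), fs)
  }, numeric(1))
  expect_lt(abs(mean(mpfs) - 2.5), 0.2)
  expect_error(median_power_frequency(rnorm(50), fs), "short")
})

test_that("MPF of a two-line spectrum matches a periodogram oracle", {
  fs <- 10
  t <- seq(0, 200, by = 1 / fs)
  # unequal powers pin the median inside the dominant line, away from the
  # knife edge between the two lines
  oracle_mpf <- function(x) {
    n <- length(x)
    p <- abs(fft(x))^2
    nf <- n %/% 2
    pg <- p[2:(nf + 1)]             # DC excluded
    fr <- (1:nf) * fs / n
    cum <- cumsum(pg) / sum(pg)
    fr[which(cum >= 0.5)[1]]
  }
  x_low <- 2 * sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)   # 80% at 1 Hz
  x_high <- sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 3 * t)  # 80% at 3 Hz
  for (x in list(x_low, x_high)) {
    mpf <- median_power_frequency(x, fs)
    expect_gt(mpf, 1 - 0.15); expect_lt(mpf, 3 + 0.15)
    expect_lt(abs(mpf - oracle_mpf(x)), 0.15)
  }
})

test_that("peak-to-peak amplitude is the mean per-cycle range", {
  fs <- 10
  # sawtooth with amplitude A per 1 s cycle
  A <- 4
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- A * (t %% 1)
  st <- seq(0, 20, by = 1)          # 20 full cycles
  expect_equal(peak_to_peak(x, st, fs), A * 0.9, tolerance = 1e-6)
  # alternating cycle amplitudes A and 2A average to 1.5A
  x2 <- x * rep(rep(c(1, 2), 10), each = fs)
  expect_equal(peak_to_peak(x2, st, fs), 1.5 * A * 0.9, tolerance = 1e-6)
  # homogeneity
  expect_equal(peak_to_peak(3 * x, st, fs), 3 * peak_to_peak(x, st, fs))
  expect_true(is.na(peak_to_peak(x, 1, fs)))
})

test_that("feature tables separate amplitude-reduced gait from healthy gait", {
  co <- make_cohort(cohort_spec(
    class_counts = c(healthy = 8, pd_ar = 8), duration_s = 60,
    master_seed = 4))
  ft <- feature_table(co)
  h <- ft[ft$class_label == "healthy", ]
  p <- ft[ft$class_label == "pd_ar", ]
  # lower RMS for akinetic-rigid gait, echoing reduced motor output
  expect_lt(mean(p$rms_gastro), mean(h$rms_gastro))
  d <- function(a, b) abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  expect_gt(d(h$rms_gastro, p$rms_gastro), 1)
  expect_gt(d(h$step_frequency, p$step_frequency), 1)
})
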