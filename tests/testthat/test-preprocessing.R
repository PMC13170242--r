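test_that("baseline removal kills DC and the stop band, preserves the pass band", {
  fs <- 10
  # constant series -> zero
  expect_lt(max(abs(remove_baseline(rep(3.7, 500), fs))), 1e-9)
  t <- seq(0, 600, by = 1 / fs)
  # 0.01 Hz drift component: attenuated below 5% RMS
  slow <- sin(2 * pi * 0.01 * t)
  expect_lt(rms(remove_baseline(slow, fs, 0.15)), 0.05 * rms(slow))
  # 1 Hz gait-band component: RMS within 2%, zero phase shift at the peak
  fast <- sin(2 * pi * 1 * t)
  out <- remove_baseline(fast, fs, 0.15)
  expect_lt(abs(rms(out) - rms(fast)) / rms(fast), 0.02)
  # zero phase: the filtered series peaks on the same sample as the input
  # (checked at one interior input peak; a causal filter would lag here)
  # (±1 sample: the true 1 Hz peak falls midway between two equal samples)
  i0 <- 2000 + which.max(fast[2001:2100])
  expect_lte(abs(which.max(out[(i0 - 3):(i0 + 3)]) - 4), 1)
  expect_gt(cor(out[1000:5000], fast[1000:5000]), 0.999)
  expect_error(remove_baseline(fast, fs, cutoff_hz = 5), "Nyquist")
  expect_error(remove_baseline(1:10, fs), "short")
})

test_that("robust normalization yields median 0 / IQR 1 and is idempotent", {
  r <- simulate_recording(default_archetypes()$healthy, 40, "S", 3)
  n1 <- robust_normalize(r)
  for (c in 1:4) {
    expect_equal(median(n1$channels[, c]), 0, tolerance = 1e-9)
    expect_equal(IQR(n1$channels[, c]), 1, tolerance = 1e-9)
  }
  n2 <- robust_normalize(n1)
  expect_equal(n2$channels, n1$channels, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("constant channels trigger the floor guard and a flag", {
  r <- simulate_recording(default_archetypes()$healthy, 20, "S", 3)
  r$channels[, 2] <- 5
  expect_message(out <- robust_normalize(r), "degenerate")
  expect_true(all(out$channels[, 2] == 0))
  expect_identical(attr(out$channels, "degenerate_channels"), "gastro")
})

test_that("median/IQR scaling resists gross outliers where mean/SD fails", {
  set.seed(8)
  x <- rnorm(2000)
  xa <- matrix(x, ncol = 1)
  xb <- xa
  out_idx <- sample(2000, 100)           # 5% gross outliers at 100x scale
  xb[out_idx, 1] <- xb[out_idx, 1] * 100
  inl <- setdiff(seq_len(2000), out_idx)
  clean <- robust_normalize(xa)[inl, 1]
  cont <- robust_normalize(xb)[inl, 1]
  expect_lt(abs(sd(cont) - sd(clean)) / sd(clean), 0.10)
  # z-scoring the contaminated series shrinks the inlier spread drastically
  z <- (xb[, 1] - mean(xb[, 1])) / sd(xb[, 1])
  expect_gt(abs(sd(z[inl]) - sd(clean)) / sd(clean), 0.5)
})

test_that("window counts follow the stride formula including boundaries", {
  mk <- function(n) {
    r <- simulate_recording(default_archetypes()$healthy, max(n / 10, 10),
                            "S", 1)
    r$channels <- r$channels[seq_len(n), , drop = FALSE]
    r
  }
  expect_equal(dim(make_windows(mk(900))$x)[1], 5)
  expect_equal(dim(make_windows(mk(300))$x)[1], 1)
  expect_warning(w0 <- make_windows(mk(299)), "shorter")
  expect_equal(dim(w0$x)[1], 0)
  # generic count formula on a sweep of lengths and overlaps
  for (n in c(300, 451, 600, 1234)) for (ov in c(0, 0.25, 0.5)) {
    ws <- make_windows(mk(n), window_len = 300, overlap_fraction = ov)
    stride <- round(300 * (1 - ov))
    expect_equal(dim(ws$x)[1], floor((n - 300) / stride) + 1)
    expect_equal(dim(ws$x)[2], 300)
    expect_true(all(ws$subject_id == "S"))
  }
})

test_that("windowing preserves subject/label provenance across a cohort", {
  co <- two_class_cohort(n_per_class = 3, duration_s = 60)
  ws <- windows_from_cohort(co)
  per_subj <- table(ws$subject_id)
  expect_true(all(per_subj == 3))  # 600 samples -> 3 windows each
  pairs <- unique(data.frame(s = ws$subject_id, l = ws$label))
  man <- co$manifest[order(co$manifest$subject_id), ]
  pairs <- pairs[order(pairs$s), ]
  expect_equal(pairs$s, man$subject_id)
  expect_equal(pairs$l, man$class_label)
})

test_that("null augmentation is the identity and lineage is inherited", {
  r <- simulate_recording(default_archetypes()$healthy, 40, "S", 3)
  ws <- make_windows(preprocess_recording(r), window_len = 100,
                     overlap_fraction = 0)
  w <- ws$x[1, , ]
  same <- augment_window(w, seed = 5, shift_max = 0, noise_sigma = 0,
                         scale_range = c(1, 1))
  expect_equal(same, w, tolerance = 1e-12)
  aug <- augment_window_set(ws, seed = 11, n_copies = 2)
  expect_equal(dim(aug$x)[1], 3 * dim(ws$x)[1])
  expect_true(all(aug$subject_id == "S"))
  expect_setequal(unique(aug$lineage),
                  c("original", "augmented_1", "augmented_2"))
  expect_error(augment_window(w[1:8, ], seed = 1), "short")
})

test_that("augmentation shifts are uniform over the 11 allowed offsets", {
  base <- seq_len(50) * 1.0   # strictly increasing ramp: shift identifiable
  counts <- integer(11)       # shifts -5..+5
  for (i in 1:10000) {
    out <- augment_window(base, seed = i, noise_sigma = 0,
                          scale_range = c(1, 1))
    s <- which.min(out) - 1L  # circular shift moves the ramp minimum
    if (s > 25) s <- s - 50L
    counts[s + 6L] <- counts[s + 6L] + 1L
  }
  expect_equal(sum(counts), 10000L)
  p <- 1 / 11
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(counts - 10000 * p) < 3 * sigma))
})
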