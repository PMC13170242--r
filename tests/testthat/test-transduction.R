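test_that("forward model obeys the zero-strain and strain-independence limits", {
  p0 <- transduction_params(I0 = 1, eta1 = 1, eta2 = 1, alpha0 = 0, k_s = 0,
                            L = 5)
  expect_equal(forward_intensity(p0, 0), 1.0)
  # with k_s = 0 the output is strain-independent
  expect_equal(forward_intensity(p0, c(0.2, 0.5, 1)), rep(1.0, 3))
  p <- transduction_params(I0 = 2, eta1 = 0.8, eta2 = 0.9, alpha0 = 0.05,
                           k_s = 0, L = 10)
  expect_equal(forward_intensity(p, 0.7), forward_intensity(p, 0))
})

test_that("log-intensity differences equal -k_s*L * strain differences", {
  p <- transduction_params(I0 = 1.5, eta1 = 0.9, eta2 = 0.85, alpha0 = 0.02,
                           k_s = 1.8, L = 3)
  eps <- seq(0, 1, length.out = 50)
  li <- log(forward_intensity(p, eps))
  # oracle: direct log of forward evaluations against the closed form
  for (i in c(2, 17, 50))
    expect_equal(li[i] - li[1], -p$k_s * p$L * (eps[i] - eps[1]),
                 tolerance = 1e-12)
  # strictly decreasing when k_s > 0
  expect_true(all(diff(forward_intensity(p, eps)) < 0))
  # degree-1 fit of ln I has residuals below 1e-12
  fit <- lm(li ~ eps)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("second-order model and input validation behave", {
  p2 <- transduction_params(I0 = 1, a1 = 2, a2 = 0.5)
  expect_equal(forward_intensity(p2, 0.5, order = 2), exp(-2 * 0.5 - 0.5 * 0.25))
  expect_error(forward_intensity(p2, -0.1), "window")
  expect_error(forward_intensity(p2, 1.2), "window")
  p1 <- transduction_params()
  expect_error(forward_intensity(p1, 0.5, order = 2), "a1")
  expect_error(transduction_params(I0 = -1), "I0")
  expect_error(transduction_params(eta1 = 1.5), "eta1")
})

test_that("fitting a noiseless linear curve recovers the generator slope exactly", {
  cv <- linear_curve(slope = 12.25, intercept = 100)
  fit <- fit_calibration(cv)
  expect_equal(fit$sensitivity, 12.25, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$degenerate)
})

test_that("constant-output curves are flagged degenerate with R^2 = 0", {
  cv <- calibration_curve(seq(0, 100, 10), rep(5, 11), rep(5, 11))
  # zero full-scale span makes the hysteresis statistic undefined
  expect_error(hysteresis_error(cv), "full-scale")
  # degenerate grid rejected
  expect_error(calibration_curve(rep(10, 5), 1:5, 1:5), "ascending")
  # fit on a flat curve: slope 0, degeneracy flag, R^2 reported as 0
  f <- fit_calibration(cv)
  expect_true(f$degenerate)
  expect_equal(f$sensitivity, 0)
  expect_equal(f$r_squared, 0)
  expect_true(is.na(f$hysteresis_max))
})

test_that("log-domain fit recovers k_s*L from simulated staircases", {
  p <- transduction_params(I0 = 2, eta1 = 0.9, eta2 = 0.9, alpha0 = 0.1,
                           k_s = 0.8, L = 2.5)
  truth <- p$k_s * p$L
  # noiseless: relative error below 1e-9
  cv <- simulate_calibration_run(p, noise_sigma_mV = 0, lag_tau_s = 0,
                                 seed = 1)
  fit <- fit_calibration(cv, domain = "log")
  expect_lt(abs(fit$sensitivity - truth) / truth, 1e-9)
})

test_that("hysteresis equals the exhaustive grid-scan oracle on random curves", {
  set.seed(42)
  for (rep in 1:200) {
    g <- seq(0, 100, by = 10)
    lo <- cumsum(runif(11, 0.5, 2)) * 50
    un <- lo + rnorm(11, 0, 20)
    cv <- calibration_curve(g, lo, un)
    h <- hysteresis_error(cv)
    # oracle: scan every grid point
    gaps <- abs(lo - un)
    vfs <- abs(lo[11] - lo[1])
    expect_equal(h$h_max, max(gaps) / vfs * 100)
    expect_equal(h$strain_at_max, g[which.max(gaps)])
  }
})

test_that("hysteresis is zero for coincident branches and ties break low", {
  cv <- linear_curve()
  expect_equal(hysteresis_error(cv)$h_max, 0)
  # equal gaps at 20% and 60% -> reported at the lowest strain
  lo <- seq(0, 1000, by = 100)
  un <- lo; un[3] <- un[3] + 50; un[7] <- un[7] + 50
  h <- hysteresis_error(calibration_curve(seq(0, 100, 10), lo, un))
  expect_equal(h$strain_at_max, 20)
})

test_that("replicates are averaged pointwise before the hysteresis scan", {
  g <- seq(0, 100, 10)
  lo <- matrix(rep(12.25 * g, 3), ncol = 3)
  un <- lo
  un[5, ] <- un[5, ] + c(30, 60, 90)  # replicate-mean gap = 60
  h <- hysteresis_error(calibration_curve(g, lo, un))
  expect_equal(h$delta_v_max, 60)
  expect_equal(h$h_max, 60 / 1225 * 100)
})

test_that("baseline drift arithmetic reports two significant figures", {
  expect_equal(baseline_drift_percent(1000, 0), 0)
  expect_equal(baseline_drift_percent(1000, 17), 1.7)
  expect_error(baseline_drift_percent(0, 5), "initial")
  expect_error(baseline_drift_percent(100, -2), "fluctuation")
})

test_that("calibration curves round-trip through CSV", {
  p <- transduction_params(k_s = 0.5, L = 2)
  cv <- simulate_calibration_run(p, noise_sigma_mV = 2, lag_tau_s = 0.5,
                                 seed = 9)
  path <- tempfile(fileext = ".csv")
  write_calibration_csv(cv, path)
  cv2 <- read_calibration_csv(path)
  expect_equal(cv2$strain_grid, cv$strain_grid)
  expect_equal(cv2$loading_output, cv$loading_output, ignore_attr = TRUE)
  expect_equal(cv2$unloading_output, cv$unloading_output, ignore_attr = TRUE)
  unlink(path)
})
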