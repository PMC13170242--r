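#' Optical strain-transduction parameters
#'
#' Physical parameters of the effective Beer-Lambert model of a stretchable
#' polymer optical strain sensor. Transmitted intensity decays exponentially
#' with the product of an attenuation coefficient and the effective fiber
#' length; tensile strain adds a loss term proportional to the extinction
#' coefficient `k_s`. Coupling efficiencies at the two plastic-fiber
#' interfaces are treated as strain-independent within the operating window.
#'
#' @param I0 Incident optical power (arbitrary optical units, > 0).
#' @param eta1,eta2 Input/output coupling efficiencies, each in (0, 1].
#' @param alpha0 Intrinsic loss coefficient (per mm, >= 0).
#' @param k_s Effective extinction coefficient (per mm per unit strain, >= 0).
#' @param L Effective fiber length (mm, > 0).
#' @param a1,a2 Optional second-order log-domain coefficients (per unit strain
#'   and per unit strain squared). Required for `order = 2` evaluation.
#' @param strain_window Operational strain window as a fraction, default
#'   `c(0, 1)` i.e. 0--100\% strain.
#' @return An object of class `transduction_params`.
#' @export
transduction_params <- function(I0 = 1, eta1 = 1, eta2 = 1, alpha0 = 0,
                                k_s = 0, L = 1, a1 = NULL, a2 = NULL,
                                strain_window = c(0, 1)) {
  assert_scalar_num(I0, "I0", lower = 0, strict_lower = TRUE)
  assert_scalar_num(eta1, "eta1", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_num(eta2, "eta2", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_num(alpha0, "alpha0", lower = 0)
  assert_scalar_num(k_s, "k_s", lower = 0)
  assert_scalar_num(L, "L", lower = 0, strict_lower = TRUE)
  if (!is.null(a1)) assert_scalar_num(a1, "a1")
  if (!is.null(a2)) assert_scalar_num(a2, "a2")
  stopifnot(length(strain_window) == 2L, strain_window[1] < strain_window[2])
  structure(
    list(I0 = I0, eta1 = eta1, eta2 = eta2, alpha0 = alpha0, k_s = k_s,
         L = L, a1 = a1, a2 = a2, strain_window = as.numeric(strain_window)),
    class = "transduction_params")
}

#' @export
print.transduction_params <- function(x, ...) {
  cat("<transduction_params>\n")
  cat(sprintf("  I0 = %g, eta1*eta2 = %g, alpha0 = %g /mm, k_s = %g /mm/strain, L = %g mm\n",
              x$I0, x$eta1 * x$eta2, x$alpha0, x$k_s, x$L))
  if (!is.null(x$a1))
    cat(sprintf("  second-order log coefficients: a1 = %g, a2 = %g\n",
                x$a1, if (is.null(x$a2)) 0 else x$a2))
  cat(sprintf("  strain window: %g to %g (fraction)\n",
              x$strain_window[1], x$strain_window[2]))
  invisible(x)
}

#' Forward strain-to-intensity model
#'
#' First-order model: `I(eps) = I0 * eta1 * eta2 * exp(-(alpha0 + k_s*eps) * L)`,
#' so `ln I` decreases linearly in strain with slope `-k_s*L`. The second-order
#' form `exp(C - a1*eps - a2*eps^2)`, with `C = ln(I0*eta1*eta2) - alpha0*L`,
#' captures the mild super-linear attenuation seen at high strain.
#'
#' @param params A [transduction_params()] object.
#' @param strain Strain as a fraction (vectorized; 0.5 = 50\% strain). Must lie
#'   within the params' operational window.
#' @param order Model order, 1 (default) or 2.
#' @return Transmitted intensity (arbitrary optical units, strictly positive).
#' @export
forward_intensity <- function(params, strain, order = 1) {
  stopifnot(inherits(params, "transduction_params"))
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2", call. = FALSE)
  if (!is.numeric(strain) || anyNA(strain))
    stop("`strain` must be numeric without NA", call. = FALSE)
  w <- params$strain_window
  if (any(strain < w[1]) || any(strain > w[2]))
    stop(sprintf("strain outside the operational window [%g, %g]", w[1], w[2]),
         call. = FALSE)
  C <- log(params$I0 * params$eta1 * params$eta2) - params$alpha0 * params$L
  if (order == 1) {
    exp(C - params$k_s * params$L * strain)
  } else {
    if (is.null(params$a1))
      stop("order 2 requires `a1` (and optionally `a2`) in the parameters",
           call. = FALSE)
    a2 <- if (is.null(params$a2)) 0 else params$a2
    exp(C - params$a1 * strain - a2 * strain^2)
  }
}

#' Staircase calibration curve
#'
#' Holds the loading and unloading output branches of a cyclic tensile
#' calibration (0 to 100\% strain in 10\% increments, repeated), as produced
#' by a stepper-motor rig sweeping the sensor through the strain grid.
#'
#' @param strain_grid Strain grid in \% strain, strictly ascending.
#' @param loading_output,unloading_output Numeric matrices (grid x replicate)
#'   of sensor output in mV; vectors are taken as a single replicate.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(strain_grid, loading_output, unloading_output) {
  strain_grid <- as.numeric(strain_grid)
  if (length(strain_grid) < 2L || is.unsorted(strain_grid, strictly = TRUE))
    stop("`strain_grid` must be strictly ascending with >= 2 points",
         call. = FALSE)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  lo <- as_mat(loading_output); un <- as_mat(unloading_output)
  if (nrow(lo) != length(strain_grid) || !identical(dim(lo), dim(un)))
    stop("branch arrays must be congruent: rows = grid points, cols = replicates",
         call. = FALSE)
  structure(list(strain_grid = strain_grid, loading_output = lo,
                 unloading_output = un, replicate_count = ncol(lo)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d strain points (%g..%g %%), %d replicate(s)\n",
              length(x$strain_grid), min(x$strain_grid), max(x$strain_grid),
              x$replicate_count))
  invisible(x)
}

#' Maximum hysteresis error of a calibration curve
#'
#' `H% = max over the grid of |V_load(eps) - V_unload(eps)| / V_FS * 100`,
#' where `V_FS = |V_load(max) - V_load(min)|` is the full-scale output span.
#' Branches are replicate-averaged pointwise before the scan; ties in the
#' maximum gap are broken toward the lowest strain.
#'
#' @param curve A [calibration_curve()].
#' @return A list with `h_max` (\%), `strain_at_max` (\% strain), and
#'   `delta_v_max` (mV, the maximum branch gap).
#' @export
hysteresis_error <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  load_mean <- rowMeans(curve$loading_output)
  unload_mean <- rowMeans(curve$unloading_output)
  v_fs <- abs(load_mean[length(load_mean)] - load_mean[1])
  if (v_fs == 0)
    stop("full-scale span is zero: loading branch endpoints coincide",
         call. = FALSE)
  gap <- abs(load_mean - unload_mean)
  i <- which.max(gap)  # which.max returns the first (lowest-strain) maximum
  list(h_max = max(gap) / v_fs * 100,
       strain_at_max = curve$strain_grid[i],
       delta_v_max = gap[i])
}

#' Fit a calibration curve
#'
#' Least-squares fit of the replicate-mean loading branch against strain.
#' In the voltage domain (default) the absolute slope is the sensor
#' sensitivity in mV per \% strain, matching how demodulated output is
#' reported. In the log domain the fit is `ln(V) ~ strain fraction`, whose
#' negative slope recovers the physical attenuation product `k_s*L` when the
#' output is proportional to transmitted intensity.
#'
#' @param curve A [calibration_curve()].
#' @param order Polynomial order of the fit, 1 (default) or 2.
#' @param domain `"voltage"` (default) or `"log"`.
#' @return An object of class `calibration_fit` with fields `sensitivity`
#'   (mV/\%; for `domain = "log"` the recovered `k_s*L`, per unit strain),
#'   `intercept`, `r_squared`, `hysteresis_max`, `hysteresis_strain`,
#'   `fit_order`, `degenerate`, and `coefficients`.
#' @export
fit_calibration <- function(curve, order = 1, domain = c("voltage", "log")) {
  stopifnot(inherits(curve, "calibration_curve"))
  domain <- match.arg(domain)
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2", call. = FALSE)
  s <- curve$strain_grid
  if (length(unique(s)) < 3L)
    stop("need >= 3 distinct strain points", call. = FALSE)
  if (order == 2 && length(unique(s)) < 4L)
    stop("order 2 requires >= 4 distinct strain points", call. = FALSE)
  y <- rowMeans(curve$loading_output)
  x <- if (domain == "log") s / 100 else s  # log fit against strain fraction
  if (domain == "log") {
    if (any(y <= 0))
      stop("log-domain fit requires strictly positive outputs", call. = FALSE)
    y <- log(y)
  }
  degenerate <- stats::var(y) == 0
  if (degenerate) {
    fit_coef <- c(mean(y), rep(0, order))
    r2 <- 0
  } else {
    fit <- if (order == 1) stats::lm(y ~ x) else stats::lm(y ~ x + I(x^2))
    fit_coef <- unname(stats::coef(fit))
    # suppress the "essentially perfect fit" note on noiseless curves
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  slope <- if (order == 1) fit_coef[2] else
    (sum(fit_coef * c(0, 1, max(x) + min(x))))  # mean slope over the span
  hyst <- tryCatch(hysteresis_error(curve), error = function(e)
    list(h_max = NA_real_, strain_at_max = NA_real_))
  structure(list(
    sensitivity = if (domain == "log") abs(slope) else abs(slope),
    intercept = fit_coef[1],
    r_squared = r2,
    hysteresis_max = hyst$h_max,
    hysteresis_strain = hyst$strain_at_max,
    fit_order = order,
    domain = domain,
    degenerate = degenerate,
    coefficients = fit_coef), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  unit <- if (x$domain == "log") "per unit strain (k_s*L)" else "mV/%"
  cat("<calibration_fit>\n")
  cat(sprintf("  sensitivity: %.4g %s%s\n", x$sensitivity, unit,
              if (x$degenerate) " [degenerate fit]" else ""))
  cat(sprintf("  R^2: %.4f   order: %d\n", x$r_squared, x$fit_order))
  cat(sprintf("  hysteresis: %.2f%% at %g%% strain\n",
              x$hysteresis_max, x$hysteresis_strain))
  invisible(x)
}

#' Baseline drift as a percentage of the initial output
#'
#' Long-exposure photo-aging metric: the maximum baseline fluctuation
#' relative to the initial zero-strain output, reported to two significant
#' figures.
#'
#' @param initial_mV Initial baseline output (mV, > 0).
#' @param max_fluctuation_mV Maximum observed fluctuation (mV, >= 0).
#' @return Drift in \%, rounded to 2 significant figures.
#' @export
baseline_drift_percent <- function(initial_mV, max_fluctuation_mV) {
  assert_scalar_num(initial_mV, "initial_mV", lower = 0, strict_lower = TRUE)
  assert_scalar_num(max_fluctuation_mV, "max_fluctuation_mV", lower = 0)
  signif(100 * max_fluctuation_mV / initial_mV, 2)
}

#' Read / write calibration curves as CSV
#'
#' Long format with columns `strain_pct`, `branch` (`load`/`unload`),
#' `replicate`, `output_mV`.
#'
#' @param curve A [calibration_curve()].
#' @param path File path.
#' @return `write_calibration_csv` returns `path` invisibly;
#'   `read_calibration_csv` returns a [calibration_curve()].
#' @export
write_calibration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  g <- length(curve$strain_grid); r <- curve$replicate_count
  df <- data.frame(
    strain_pct = rep(curve$strain_grid, times = 2 * r),
    branch = rep(c("load", "unload"), each = g * r),
    replicate = rep(rep(seq_len(r), each = g), times = 2),
    output_mV = c(as.vector(curve$loading_output),
                  as.vector(curve$unloading_output)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("strain_pct", "branch", "replicate", "output_mV")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  grid <- sort(unique(df$strain_pct))
  reps <- sort(unique(df$replicate))
  pick <- function(br) {
    m <- matrix(NA_real_, length(grid), length(reps))
    sub <- df[df$branch == br, ]
    m[cbind(match(sub$strain_pct, grid), match(sub$replicate, reps))] <-
      sub$output_mV
    m
  }
  calibration_curve(grid, pick("load"), pick("unload"))
}
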