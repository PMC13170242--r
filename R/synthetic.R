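#' Gait archetype parameters
#'
#' Phenomenological per-class signal model for the synthetic cohort: a
#' plantar-pressure channel carrying one biphasic (contact--separation)
#' pulse per step, and three muscle-strain channels carrying one smooth
#' per-cycle bump each, with class-specific cadence, variability, amplitude,
#' asymmetry, tremor, and freezing-of-gait structure.
#'
#' Classes: `healthy`; `hemi_left` / `hemi_right` (post-stroke hemiplegia,
#' alternate-step amplitude and duration asymmetry); `pd_td`
#' (tremor-dominant Parkinson's, tremor overlay on the strain channels);
#' `pd_ar` (akinetic-rigid, globally reduced amplitude); `pd_pigd`
#' (postural-instability/gait-difficulty, freezing episodes that delete
#' steps).
#'
#' @param class_label One of `healthy`, `hemi_left`, `hemi_right`, `pd_td`,
#'   `pd_ar`, `pd_pigd` (free labels are allowed for custom cohorts).
#' @param step_frequency_hz Mean step frequency (Hz, must be < Nyquist).
#' @param step_interval_cv Step-interval coefficient of variation (\%).
#' @param amplitude_scale Length-4 amplitude multiplier per channel
#'   (plantar, gastrocnemius, vastus medialis, biceps femoris); a scalar is
#'   recycled.
#' @param asymmetry_ratio Alternate-step ratio in (0, 1]: the affected side's
#'   strain-bump amplitude is scaled by this ratio and the alternate cycle
#'   durations are split so their ratio equals it (mean cadence preserved).
#' @param affected_parity Which alternate-step parity is attenuated
#'   (`"odd"` or `"even"`); encodes hemiplegia side.
#' @param freeze_rate Freezing episodes per minute (>= 0).
#' @param freeze_duration_s Duration of each freezing episode (s).
#' @param tremor_hz Tremor frequency (Hz, must be < Nyquist; 0 = none).
#' @param tremor_amp Tremor amplitude on the strain channels (robust units).
#' @param noise_sigma Additive Gaussian noise SD (robust units).
#' @param drift_sigma Random-walk drift step SD per sample.
#' @return An object of class `archetype_params`.
#' @export
archetype_params <- function(class_label,
                             step_frequency_hz = 0.9,
                             step_interval_cv = 5,
                             amplitude_scale = 1,
                             asymmetry_ratio = 1,
                             affected_parity = c("odd", "even"),
                             freeze_rate = 0,
                             freeze_duration_s = 5,
                             tremor_hz = 0,
                             tremor_amp = 0,
                             noise_sigma = 0.05,
                             drift_sigma = 0.002) {
  affected_parity <- match.arg(affected_parity)
  assert_scalar_num(step_frequency_hz, "step_frequency_hz", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(step_interval_cv, "step_interval_cv", lower = 0)
  assert_scalar_num(asymmetry_ratio, "asymmetry_ratio", lower = 0, upper = 1,
                    strict_lower = TRUE)
  assert_scalar_num(freeze_rate, "freeze_rate", lower = 0)
  assert_scalar_num(freeze_duration_s, "freeze_duration_s", lower = 0)
  assert_scalar_num(tremor_hz, "tremor_hz", lower = 0)
  assert_scalar_num(tremor_amp, "tremor_amp", lower = 0)
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar_num(drift_sigma, "drift_sigma", lower = 0)
  if (length(amplitude_scale) == 1) amplitude_scale <- rep(amplitude_scale, 4)
  stopifnot(length(amplitude_scale) == 4, all(amplitude_scale >= 0))
  structure(list(class_label = as.character(class_label),
                 step_frequency_hz = step_frequency_hz,
                 step_interval_cv = step_interval_cv,
                 amplitude_scale = amplitude_scale,
                 asymmetry_ratio = asymmetry_ratio,
                 affected_parity = affected_parity,
                 freeze_rate = freeze_rate,
                 freeze_duration_s = freeze_duration_s,
                 tremor_hz = tremor_hz, tremor_amp = tremor_amp,
                 noise_sigma = noise_sigma, drift_sigma = drift_sigma),
            class = "archetype_params")
}

#' Default archetypes for the six-class cohort
#'
#' Defaults are phenomenological choices, not clinical claims: hemiplegic
#' classes carry marked alternate-step asymmetry and slowed, more variable
#' cadence; tremor-dominant Parkinson's adds a 3.5 Hz tremor overlay (kept
#' below the 5 Hz Nyquist limit of the 10 Hz recordings); akinetic-rigid
#' halves signal amplitude; the PIGD subtype inserts freezing episodes.
#'
#' @return Named list of [archetype_params()] objects.
#' @export
default_archetypes <- function() {
  list(
    healthy = archetype_params("healthy", step_frequency_hz = 0.9,
                               step_interval_cv = 5, amplitude_scale = 1),
    hemi_left = archetype_params("hemi_left", step_frequency_hz = 0.7,
                                 step_interval_cv = 12,
                                 amplitude_scale = 0.9,
                                 asymmetry_ratio = 0.55,
                                 affected_parity = "odd"),
    hemi_right = archetype_params("hemi_right", step_frequency_hz = 0.7,
                                  step_interval_cv = 12,
                                  amplitude_scale = 0.9,
                                  asymmetry_ratio = 0.55,
                                  affected_parity = "even"),
    pd_td = archetype_params("pd_td", step_frequency_hz = 0.8,
                             step_interval_cv = 10, amplitude_scale = 0.8,
                             tremor_hz = 3.5, tremor_amp = 0.25),
    pd_ar = archetype_params("pd_ar", step_frequency_hz = 0.75,
                             step_interval_cv = 10, amplitude_scale = 0.5),
    pd_pigd = archetype_params("pd_pigd", step_frequency_hz = 0.8,
                               step_interval_cv = 15, amplitude_scale = 0.8,
                               freeze_rate = 2, freeze_duration_s = 5))
}

#' Relative triboelectric pulse amplitude versus contact force
#'
#' Monotone saturating (logarithmic) curve anchored at 500 relative units at
#' 1 N and 1150 at 40 N, used only to shape simulated plantar pulses.
#'
#' @param force_N Contact force (N, > 0; vectorized).
#' @return Relative amplitude.
#' @export
teng_amplitude_from_force <- function(force_N) {
  if (!is.numeric(force_N) || any(!is.finite(force_N)) || any(force_N <= 0))
    stop("`force_N` must be positive", call. = FALSE)
  500 + 650 * log(force_N) / log(40)
}

channel_names <- function() c("plantar", "gastro", "vastus", "biceps")

#' Simulate one 4-channel gait recording
#'
#' Draws step times (Gaussian intervals around the archetype cadence,
#' alternate-cycle split for hemiplegic asymmetry, freezing-episode
#' deletions), then renders a biphasic triboelectric pulse per step on the
#' plantar channel and phase-offset smooth strain bumps per gait cycle on
#' the three muscle channels, adds tremor where configured, and finally adds
#' Gaussian noise and random-walk baseline drift. Identical
#' (archetype, duration, seed) inputs give bit-identical output.
#'
#' @param archetype An [archetype_params()] object.
#' @param duration_s Recording duration (s, >= 10).
#' @param subject_id Subject identifier carried on the recording.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate (Hz), default 10.
#' @return An object of class `gait_recording`: list with `sample_rate`,
#'   `channels` (n x 4 matrix, columns plantar/gastro/vastus/biceps),
#'   `subject_id`, `class_label`, `true_step_times`.
#' @export
simulate_recording <- function(archetype, duration_s, subject_id, seed,
                               sample_rate = 10) {
  stopifnot(inherits(archetype, "archetype_params"))
  assert_scalar_num(duration_s, "duration_s", lower = 10)
  assert_scalar_num(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (archetype$tremor_hz >= sample_rate / 2)
    stop("tremor_hz must be below the Nyquist frequency", call. = FALSE)
  if (archetype$step_frequency_hz >= sample_rate / 2)
    stop("step_frequency_hz must be below the Nyquist frequency",
         call. = FALSE)
  with_seed(seed, {
    n <- round(duration_s * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    mu <- 1 / archetype$step_frequency_hz
    sd_iv <- archetype$step_interval_cv / 100 * mu
    r <- archetype$asymmetry_ratio

    # step times: base Gaussian intervals, then alternate-cycle split so the
    # odd/even duration ratio equals the asymmetry ratio (mean preserved)
    n_max <- ceiling(duration_s / mu * 2.5) + 10
    base <- stats::rnorm(n_max, mu, sd_iv)
    base <- pmax(base, 0.1)
    mult <- rep(c(2 / (1 + r), 2 * r / (1 + r)), length.out = n_max)
    if (archetype$affected_parity == "even")
      mult <- rep(c(2 * r / (1 + r), 2 / (1 + r)), length.out = n_max)
    intervals <- base * mult
    steps <- 1 + cumsum(intervals)
    parity <- rep(c(1L, 2L), length.out = n_max)  # 1 = odd cycle, 2 = even
    keep <- steps < duration_s - 0.5
    steps <- steps[keep]; parity <- parity[keep]

    # freezing-of-gait: delete steps inside Poisson-placed episodes
    if (archetype$freeze_rate > 0 && length(steps) > 0) {
      n_ep <- stats::rpois(1, archetype$freeze_rate * duration_s / 60)
      if (n_ep > 0) {
        starts <- stats::runif(n_ep, 0,
                               max(duration_s - archetype$freeze_duration_s, 0))
        frozen <- rep(FALSE, length(steps))
        for (s0 in starts)
          frozen <- frozen |
            (steps >= s0 & steps <= s0 + archetype$freeze_duration_s)
        steps <- steps[!frozen]; parity <- parity[!frozen]
      }
    }

    amp <- archetype$amplitude_scale
    x <- matrix(0, n, 4, dimnames = list(NULL, channel_names()))

    # plantar: biphasic pulse (positive then negative lobe), difference of two
    # Gaussians of width 0.08 s reflecting contact--separation polarity
    w <- 0.08; lobe_gap <- 0.2
    for (ti in steps) {
      idx <- which(abs(t - ti) < 1.2)
      x[idx, 1] <- x[idx, 1] + amp[1] *
        (exp(-(t[idx] - ti)^2 / (2 * w^2)) -
           exp(-(t[idx] - ti - lobe_gap)^2 / (2 * w^2)))
    }

    # strain channels: one smooth Gaussian bump per gait cycle with
    # channel-specific phase offsets; affected-parity cycles attenuated
    phase <- c(0.15, 0.40, 0.65)  # gastro, vastus, biceps (fraction of cycle)
    affected <- if (archetype$affected_parity == "odd") 1L else 2L
    if (length(steps) >= 2) {
      for (i in seq_len(length(steps) - 1)) {
        cyc <- steps[i + 1] - steps[i]
        gain <- if (parity[i] == affected) r else 1
        for (c in 1:3) {
          center <- steps[i] + phase[c] * cyc
          bw <- 0.15 * cyc
          idx <- which(t > center - 4 * bw & t < center + 4 * bw)
          x[idx, c + 1] <- x[idx, c + 1] + amp[c + 1] * gain *
            exp(-(t[idx] - center)^2 / (2 * bw^2))
        }
      }
    }

    if (archetype$tremor_amp > 0 && archetype$tremor_hz > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      for (c in 1:3)
        x[, c + 1] <- x[, c + 1] +
          archetype$tremor_amp * sin(2 * pi * archetype$tremor_hz * t + ph[c])
    }

    if (archetype$noise_sigma > 0)
      x <- x + matrix(stats::rnorm(n * 4, 0, archetype$noise_sigma), n, 4)
    if (archetype$drift_sigma > 0)
      for (c in 1:4)
        x[, c] <- x[, c] + cumsum(stats::rnorm(n, 0, archetype$drift_sigma))

    structure(list(sample_rate = sample_rate, channels = x,
                   subject_id = as.character(subject_id),
                   class_label = archetype$class_label,
                   true_step_times = steps),
              class = "gait_recording")
  })
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> subject %s (%s): %d samples x 4 channels @ %g Hz, %d steps\n",
    x$subject_id, x$class_label, nrow(x$channels), x$sample_rate,
    length(x$true_step_times)))
  invisible(x)
}

#' Cohort specification
#'
#' Default composition mirrors a 60-subject study: 15 healthy controls,
#' 15 left and 15 right hemiplegia, and 15 Parkinson's split evenly over the
#' tremor-dominant, akinetic-rigid, and PIGD subtypes.
#'
#' @param class_counts Named integer vector of subjects per class; names must
#'   match archetype names.
#' @param duration_s Per-subject recording duration (s).
#' @param master_seed Integer master seed; per-subject seeds are derived
#'   deterministically from it.
#' @param archetypes Named list of [archetype_params()] (default
#'   [default_archetypes()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(class_counts = c(healthy = 15, hemi_left = 15,
                                         hemi_right = 15, pd_td = 5,
                                         pd_ar = 5, pd_pigd = 5),
                        duration_s = 90, master_seed = 1,
                        archetypes = default_archetypes()) {
  stopifnot(!is.null(names(class_counts)), all(class_counts >= 0),
            all(names(class_counts) %in% names(archetypes)))
  assert_scalar_num(duration_s, "duration_s", lower = 10)
  structure(list(class_counts = class_counts, duration_s = duration_s,
                 master_seed = as.integer(master_seed),
                 archetypes = archetypes),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' One recording per subject; subject IDs are unique and per-subject seeds
#' derive deterministically from the master seed, so two cohorts built from
#' the same spec are identical.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `gait_cohort`: list with `recordings` (named
#'   list of [simulate_recording()] outputs) and `manifest` (data.frame of
#'   subject_id, class_label, seed).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- spec$class_counts[spec$class_counts > 0]
  labels <- rep(names(counts), times = counts)
  ids <- sprintf("S%03d", seq_along(labels))
  seeds <- vapply(ids, function(id) derive_seed(spec$master_seed, id),
                  integer(1))
  recs <- vector("list", length(ids)); names(recs) <- ids
  for (i in seq_along(ids))
    recs[[i]] <- simulate_recording(spec$archetypes[[labels[i]]],
                                    spec$duration_s, ids[i], seeds[i])
  structure(list(
    recordings = recs,
    manifest = data.frame(subject_id = ids, class_label = labels,
                          seed = unname(seeds), stringsAsFactors = FALSE),
    spec = spec), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects, %g s each @ %g Hz\n",
              nrow(x$manifest), x$spec$duration_s,
              x$recordings[[1]]$sample_rate))
  print(table(x$manifest$class_label))
  invisible(x)
}

#' Simulate a staircase calibration run
#'
#' Sweeps the forward transduction model through the 0--100\% strain grid
#' (loading then unloading), maps intensity to mV through a linear gain, and
#' applies a first-order sensor lag (time constant `lag_tau_s` per `dwell_s`
#' dwell at each grid point) that opens a loading/unloading gap, plus
#' additive Gaussian noise per replicate. With zero lag and zero noise the
#' two branches coincide.
#'
#' @param params A [transduction_params()] object.
#' @param noise_sigma_mV Additive noise SD (mV, >= 0).
#' @param lag_tau_s First-order lag time constant (s, >= 0).
#' @param seed Integer seed.
#' @param grid Strain grid in \% (default 0..100 by 10).
#' @param replicates Number of repeated sweeps (default 3).
#' @param gain_mV Output gain (mV per intensity unit, default 1000).
#' @param dwell_s Dwell time per grid point (s, default 1).
#' @return A [calibration_curve()].
#' @export
simulate_calibration_run <- function(params, noise_sigma_mV = 0,
                                     lag_tau_s = 0, seed = 1,
                                     grid = seq(0, 100, by = 10),
                                     replicates = 3, gain_mV = 1000,
                                     dwell_s = 1) {
  stopifnot(inherits(params, "transduction_params"))
  assert_scalar_num(noise_sigma_mV, "noise_sigma_mV", lower = 0)
  assert_scalar_num(lag_tau_s, "lag_tau_s", lower = 0)
  stopifnot(replicates >= 1)
  target <- gain_mV * forward_intensity(params, grid / 100)
  alpha <- if (lag_tau_s > 0) 1 - exp(-dwell_s / lag_tau_s) else 1
  g <- length(grid)
  v <- target[1]
  load_true <- unload_true <- numeric(g)
  for (i in seq_len(g)) {                   # loading sweep 0 -> 100
    v <- v + alpha * (target[i] - v)
    load_true[i] <- v
  }
  for (i in rev(seq_len(g))) {              # unloading sweep 100 -> 0
    v <- v + alpha * (target[i] - v)
    unload_true[i] <- v
  }
  with_seed(seed, {
    lo <- matrix(load_true, g, replicates) +
      matrix(stats::rnorm(g * replicates, 0, noise_sigma_mV), g, replicates)
    un <- matrix(unload_true, g, replicates) +
      matrix(stats::rnorm(g * replicates, 0, noise_sigma_mV), g, replicates)
    calibration_curve(grid, lo, un)
  })
}

#' Write / read a gait recording as CSV + JSON sidecar
#'
#' CSV columns: `t_s`, `plantar`, `gastro`, `vastus`, `biceps`. The JSON
#' sidecar (same path with extension `.json`) carries subject ID, class
#' label, sampling rate, and ground-truth step times.
#'
#' @param rec A `gait_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `gait_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  n <- nrow(rec$channels)
  df <- data.frame(t_s = (seq_len(n) - 1) / rec$sample_rate, rec$channels)
  utils::write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, class_label = rec$class_label,
         sample_rate = rec$sample_rate,
         true_step_times = rec$true_step_times),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  x <- as.matrix(df[, channel_names()])
  structure(list(sample_rate = side$sample_rate, channels = x,
                 subject_id = side$subject_id,
                 class_label = side$class_label,
                 true_step_times = as.numeric(side$true_step_times)),
            class = "gait_recording")
}
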