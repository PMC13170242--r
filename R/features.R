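#' Detect steps on the plantar-pressure channel
#'
#' Local maxima with topographic prominence of at least
#' `prominence_factor` times the channel's robust amplitude scale, thinned
#' so that retained peaks are separated by at least `min_separation_s`
#' (higher peaks win). The robust scale is the 99th-percentile height above
#' the median, which tracks pulse amplitude even for sparse spike trains
#' whose MAD reflects only baseline noise. Expects a mean-subtracted
#' series.
#'
#' @param plantar_series Numeric vector (mean-subtracted plantar channel).
#' @param sample_rate Sampling rate (Hz).
#' @param prominence_factor Prominence threshold in robust-scale units
#'   (default 0.5).
#' @param min_separation_s Minimum peak separation (s, default 0.3).
#' @return Strictly increasing step times (s); empty for flat input.
#' @export
detect_steps <- function(plantar_series, sample_rate,
                         prominence_factor = 0.5, min_separation_s = 0.3) {
  x <- as.numeric(plantar_series)
  n <- length(x)
  if (n < 3) return(numeric(0))
  scale <- stats::quantile(x, 0.99, names = FALSE) - stats::median(x)
  if (!is.finite(scale) || scale <= 0) scale <- stats::mad(x)
  if (is.na(scale) || scale == 0) return(numeric(0))
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] &
                     x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(is_peak) == 0) return(numeric(0))
  prom <- vapply(is_peak, function(i) peak_prominence(x, i), numeric(1))
  keep <- is_peak[prom >= prominence_factor * scale]
  if (length(keep) == 0) return(numeric(0))
  # greedy thinning: visit by descending height, enforce min separation
  min_gap <- min_separation_s * sample_rate
  ord <- keep[order(x[keep], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord)
    if (all(abs(accepted - i) >= min_gap)) accepted <- c(accepted, i)
  sort((accepted - 1) / sample_rate)
}

# Topographic prominence of the peak at index i: height above the higher of
# the two key saddles (lowest point between the peak and the nearest higher
# peak, or the series edge).
peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]; j <- i
  while (j > 1 && x[j - 1] <= x[i]) {
    j <- j - 1
    if (x[j] < left_min) left_min <- x[j]
  }
  if (j == 1) left_min <- min(x[1:i])
  right_min <- x[i]; j <- i
  while (j < n && x[j + 1] <= x[i]) {
    j <- j + 1
    if (x[j] > -Inf && x[j] < right_min) right_min <- x[j]
  }
  if (j == n) right_min <- min(x[i:n])
  x[i] - max(left_min, right_min)
}

#' Step-interval statistics
#'
#' From step times: step frequency (1 / mean interval), interval coefficient
#' of variation (100 * SD / mean), and a symmetry index comparing alternate
#' (odd/even) cycle durations as a left/right proxy:
#' `min(mA, mB) / max(mA, mB)` where `mA`, `mB` are the mean durations of
#' odd and even cycles.
#'
#' @param step_times Strictly increasing step times (s).
#' @return List with `step_frequency` (Hz), `step_interval_cv` (\%),
#'   `symmetry_index` (in (0, 1]), `step_count`. Fields that need more steps
#'   than supplied (CV: >= 3 steps, symmetry: >= 4) are `NA`.
#' @export
interval_stats <- function(step_times) {
  st <- as.numeric(step_times)
  if (length(st) >= 2 && any(diff(st) <= 0))
    stop("`step_times` must be strictly increasing", call. = FALSE)
  out <- list(step_frequency = NA_real_, step_interval_cv = NA_real_,
              symmetry_index = NA_real_, step_count = length(st))
  if (length(st) < 2) return(out)
  iv <- diff(st)
  out$step_frequency <- 1 / mean(iv)
  if (length(st) >= 3)
    out$step_interval_cv <- 100 * stats::sd(iv) / mean(iv)
  if (length(st) >= 4) {
    odd <- iv[seq(1, length(iv), by = 2)]
    even <- iv[seq(2, length(iv), by = 2)]
    ma <- mean(odd); mb <- mean(even)
    out$symmetry_index <- min(ma, mb) / max(ma, mb)
  }
  out
}

#' Root mean square of a signal
#'
#' @param series Nonempty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(series) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  sqrt(mean(as.numeric(series)^2))
}

#' Welch power spectral density
#'
#' Hann-windowed overlapping segments, periodograms averaged.
#'
#' @param series Numeric vector, at least one segment long.
#' @param sample_rate Sampling rate (Hz).
#' @param segment_len Segment length (samples, default 128).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return List with `freq` (Hz, one-sided including DC) and `psd`.
#' @export
welch_psd <- function(series, sample_rate, segment_len = 128, overlap = 0.5) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < segment_len)
    stop("series shorter than one PSD segment", call. = FALSE)
  step <- max(1L, as.integer(round(segment_len * (1 - overlap))))
  starts <- seq(1L, n - segment_len + 1L, by = step)
  win <- as.numeric(signal::hanning(segment_len))
  wnorm <- sum(win^2)
  nf <- segment_len %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_len - 1)] * win
    p <- abs(stats::fft(seg))^2 / (wnorm * sample_rate)
    acc <- acc + p[1:nf]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]  # fold negative frequencies
  list(freq = (0:(nf - 1)) * sample_rate / segment_len, psd = psd)
}

#' Median power frequency
#'
#' Smallest frequency at which the cumulative Welch power (DC bin excluded)
#' reaches half the total, linearly interpolated between spectral bins.
#'
#' @param series Numeric vector, at least `segment_len` samples.
#' @param sample_rate Sampling rate (Hz).
#' @param segment_len,overlap Passed to [welch_psd()].
#' @return Median power frequency (Hz).
#' @export
median_power_frequency <- function(series, sample_rate, segment_len = 128,
                                   overlap = 0.5) {
  w <- welch_psd(series, sample_rate, segment_len, overlap)
  f <- w$freq[-1]; p <- w$psd[-1]   # exclude the DC bin
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  cs <- cumsum(p)
  half <- tot / 2
  i <- which(cs >= half)[1]
  if (i == 1) return(f[1])
  # linear interpolation of the cumulative power between bins i-1 and i
  f[i - 1] + (half - cs[i - 1]) / (cs[i] - cs[i - 1]) * (f[i] - f[i - 1])
}

#' Mean per-cycle peak-to-peak amplitude
#'
#' Mean over gait cycles (intervals between consecutive step times) of the
#' within-cycle max minus min.
#'
#' @param series Numeric vector.
#' @param step_times Step times (s); at least 2.
#' @param sample_rate Sampling rate (Hz).
#' @return Mean per-cycle peak-to-peak amplitude; `NA` with fewer than
#'   2 steps.
#' @export
peak_to_peak <- function(series, step_times, sample_rate) {
  x <- as.numeric(series)
  st <- as.numeric(step_times)
  if (length(st) < 2) return(NA_real_)
  ranges <- vapply(seq_len(length(st) - 1), function(i) {
    a <- max(1L, as.integer(floor(st[i] * sample_rate)) + 1L)
    b <- min(length(x), as.integer(floor(st[i + 1] * sample_rate)) + 1L)
    seg <- x[a:b]
    max(seg) - min(seg)
  }, numeric(1))
  mean(ranges)
}

#' Gait feature vector of one recording
#'
#' Computes the full metric set on a (typically preprocessed) recording:
#' per-channel RMS, median power frequency of the strain channels, step
#' frequency / interval CV / symmetry from detected (or supplied) steps, and
#' mean per-cycle peak-to-peak amplitude of the plantar channel.
#'
#' @param recording A `gait_recording`.
#' @param step_times Optional step times; detected with [detect_steps()]
#'   when `NULL`.
#' @param mpf_segment_len Welch segment length (default 128, shrunk to the
#'   recording length if needed).
#' @return One-row `data.frame` of features.
#' @export
gait_features <- function(recording, step_times = NULL,
                          mpf_segment_len = 128) {
  stopifnot(inherits(recording, "gait_recording"))
  x <- recording$channels
  fs <- recording$sample_rate
  if (is.null(step_times))
    step_times <- detect_steps(x[, 1] - mean(x[, 1]), fs)
  iv <- interval_stats(step_times)
  seg <- min(mpf_segment_len, nrow(x))
  df <- data.frame(
    subject_id = recording$subject_id,
    class_label = recording$class_label,
    rms_plantar = rms(x[, 1]), rms_gastro = rms(x[, 2]),
    rms_vastus = rms(x[, 3]), rms_biceps = rms(x[, 4]),
    mpf_gastro = median_power_frequency(x[, 2], fs, seg),
    mpf_vastus = median_power_frequency(x[, 3], fs, seg),
    mpf_biceps = median_power_frequency(x[, 4], fs, seg),
    step_frequency = iv$step_frequency,
    step_interval_cv = iv$step_interval_cv,
    symmetry_index = iv$symmetry_index,
    p2p_plantar = peak_to_peak(x[, 1], step_times, fs),
    step_count = iv$step_count,
    stringsAsFactors = FALSE)
  df
}

#' Feature table of a cohort
#'
#' One row per subject. Recordings are baseline-corrected first (features
#' are computed in sensor units, not robust-normalized ones, so that
#' amplitude-borne class signatures such as the reduced RMS of akinetic-rigid
#' gait are preserved).
#'
#' @param cohort A `gait_cohort`.
#' @param baseline_correct Apply [baseline_correct_recording()] first
#'   (default TRUE).
#' @param cutoff_hz High-pass cutoff for baseline correction.
#' @return `data.frame` with one row per subject.
#' @export
feature_table <- function(cohort, baseline_correct = TRUE, cutoff_hz = 0.15) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- lapply(cohort$recordings, function(r) {
    if (baseline_correct) r <- baseline_correct_recording(r, cutoff_hz)
    gait_features(r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Step-count relative error versus a reference count
#'
#' `100 * |n_hat - n_ref| / n_ref`, the comparison statistic used to
#' validate wearable step counting against a reference counter.
#'
#' @param n_hat Detected step count.
#' @param n_ref Reference step count (> 0).
#' @return Relative error in \%.
#' @export
step_count_error <- function(n_hat, n_ref) {
  assert_scalar_num(n_ref, "n_ref", lower = 0, strict_lower = TRUE)
  100 * abs(n_hat - n_ref) / n_ref
}
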