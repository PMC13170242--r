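#' Baseline removal: mean subtraction + zero-phase Butterworth high-pass
#'
#' Subtracts the series mean, then applies a fourth-order Butterworth
#' high-pass forward and backward (zero-phase, via [signal::filtfilt()]) to
#' suppress drift and low-frequency motion artifacts without phase
#' distortion. Output length equals input length.
#'
#' @param series Numeric vector.
#' @param sample_rate Sampling rate (Hz).
#' @param cutoff_hz High-pass cutoff (Hz); must lie in (0, Nyquist).
#' @param filter_order Butterworth design order (default 4).
#' @return Filtered numeric vector of the same length.
#' @export
remove_baseline <- function(series, sample_rate, cutoff_hz = 0.15,
                            filter_order = 4) {
  if (!is.numeric(series)) stop("`series` must be numeric", call. = FALSE)
  if (length(series) <= 3 * filter_order)
    stop("series too short for the requested filter order", call. = FALSE)
  nyq <- sample_rate / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("`cutoff_hz` must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  x <- series - mean(series)
  bf <- signal::butter(filter_order, cutoff_hz / nyq, type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Robust median/IQR normalization of a recording
#'
#' Per channel: `(x - median) / max(IQR, floor)`. After normalization every
#' non-degenerate channel has median 0 and IQR 1, harmonizing amplitude
#' ranges across participants while resisting gross outliers. Constant
#' channels hit the floor guard, come out all-zero, and are flagged.
#'
#' @param recording A `gait_recording` (or a plain numeric matrix).
#' @param iqr_floor Lower bound on the IQR divisor (default 1e-6).
#' @return The recording with normalized channels; degenerate channels (if
#'   any) are listed in the `degenerate_channels` attribute of the channel
#'   matrix and reported via [message()].
#' @export
robust_normalize <- function(recording, iqr_floor = 1e-6) {
  mat_in <- is.matrix(recording)
  x <- if (mat_in) recording else recording$channels
  degen <- character(0)
  for (c in seq_len(ncol(x))) {
    med <- stats::median(x[, c])
    iqr <- stats::IQR(x[, c])
    if (iqr <= iqr_floor)
      degen <- c(degen, colnames(x)[c] %||% as.character(c))
    x[, c] <- (x[, c] - med) / max(iqr, iqr_floor)
  }
  if (length(degen) > 0) {
    message("robust_normalize: degenerate (near-constant) channel(s): ",
            paste(degen, collapse = ", "))
    attr(x, "degenerate_channels") <- degen
  }
  if (mat_in) return(x)
  recording$channels <- x
  recording
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-correct a recording
#'
#' The three muscle-strain channels are baseline-corrected (mean subtraction
#' + zero-phase high-pass); the plantar channel, whose pulses are broadband,
#' gets mean subtraction only.
#'
#' @param recording A `gait_recording`.
#' @param cutoff_hz High-pass cutoff for the strain channels (Hz).
#' @return The baseline-corrected `gait_recording` (amplitudes preserved).
#' @export
baseline_correct_recording <- function(recording, cutoff_hz = 0.15) {
  stopifnot(inherits(recording, "gait_recording"))
  x <- recording$channels
  x[, 1] <- x[, 1] - mean(x[, 1])
  for (c in 2:4)
    x[, c] <- remove_baseline(x[, c], recording$sample_rate, cutoff_hz)
  recording$channels <- x
  recording
}

#' Full classifier preprocessing of a recording
#'
#' [baseline_correct_recording()] followed by [robust_normalize()]. The
#' normalization harmonizes amplitude ranges across participants for the
#' classifier; gait feature statistics are computed on baseline-corrected
#' (unnormalized) signals instead, so that amplitude-borne clinical
#' signatures survive.
#'
#' @param recording A `gait_recording`.
#' @param cutoff_hz High-pass cutoff for the strain channels (Hz).
#' @return The preprocessed `gait_recording`.
#' @export
preprocess_recording <- function(recording, cutoff_hz = 0.15) {
  robust_normalize(baseline_correct_recording(recording, cutoff_hz))
}

#' Segment a recording into fixed-length overlapping windows
#'
#' Stride is `round(window_len * (1 - overlap_fraction))`; the number of
#' windows is `floor((N - window_len) / stride) + 1` for `N >= window_len`,
#' else 0. Every window carries the recording's subject ID and class label.
#'
#' @param recording A `gait_recording`.
#' @param window_len Window length in samples (default 300, i.e. 30 s at
#'   10 Hz).
#' @param overlap_fraction Overlap between consecutive windows in [0, 1)
#'   (default 0.5).
#' @return An object of class `window_set`: list with `x` (array
#'   n_windows x window_len x n_channels), `subject_id`, `label`, `source`
#'   (recording id), `lineage` (`"original"` here), `window_len`,
#'   `sample_rate`, `channel_names`.
#' @export
make_windows <- function(recording, window_len = 300, overlap_fraction = 0.5) {
  stopifnot(inherits(recording, "gait_recording"))
  if (window_len < 2) stop("`window_len` must be >= 2", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  n <- nrow(recording$channels)
  stride <- max(1L, as.integer(round(window_len * (1 - overlap_fraction))))
  if (n < window_len) {
    warning(sprintf("recording %s shorter than the window (%d < %d): no windows",
                    recording$subject_id, n, window_len))
    k <- 0L
  } else {
    k <- as.integer((n - window_len) %/% stride + 1)
  }
  nc <- ncol(recording$channels)
  x <- array(0, dim = c(k, window_len, nc))
  if (k > 0)
    for (i in seq_len(k)) {
      at <- (i - 1L) * stride
      x[i, , ] <- recording$channels[(at + 1):(at + window_len), ]
    }
  structure(list(
    x = x,
    subject_id = rep(recording$subject_id, k),
    label = rep(recording$class_label, k),
    source = rep(recording$subject_id, k),
    lineage = rep("original", k),
    window_len = as.integer(window_len),
    sample_rate = recording$sample_rate,
    channel_names = colnames(recording$channels) %||% channel_names()),
    class = "window_set")
}

#' Concatenate window sets
#'
#' @param ... `window_set` objects (or a single list of them).
#' @return A combined `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  sets <- Filter(function(s) dim(s$x)[1] > 0, sets)
  if (length(sets) == 0) stop("no non-empty window sets to bind", call. = FALSE)
  wl <- unique(vapply(sets, function(s) s$window_len, integer(1)))
  stopifnot(length(wl) == 1)
  nc <- unique(vapply(sets, function(s) dim(s$x)[3], numeric(1)))
  stopifnot(length(nc) == 1)
  ks <- vapply(sets, function(s) dim(s$x)[1], numeric(1))
  x <- array(0, dim = c(sum(ks), wl, nc))
  at <- 0
  for (s in sets) {
    k <- dim(s$x)[1]
    if (k > 0) x[(at + 1):(at + k), , ] <- s$x
    at <- at + k
  }
  structure(list(
    x = x,
    subject_id = unlist(lapply(sets, `[[`, "subject_id")),
    label = unlist(lapply(sets, `[[`, "label")),
    source = unlist(lapply(sets, `[[`, "source")),
    lineage = unlist(lapply(sets, `[[`, "lineage")),
    window_len = wl,
    sample_rate = sets[[1]]$sample_rate,
    channel_names = sets[[1]]$channel_names), class = "window_set")
}

#' Preprocess and window a whole cohort
#'
#' @param cohort A `gait_cohort`.
#' @param window_len,overlap_fraction Passed to [make_windows()].
#' @param cutoff_hz Passed to [preprocess_recording()].
#' @return A combined `window_set` over all subjects.
#' @export
windows_from_cohort <- function(cohort, window_len = 300,
                                overlap_fraction = 0.5, cutoff_hz = 0.15) {
  stopifnot(inherits(cohort, "gait_cohort"))
  sets <- lapply(cohort$recordings, function(r)
    make_windows(preprocess_recording(r, cutoff_hz), window_len,
                 overlap_fraction))
  bind_windows(sets)
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<window_set> %d windows x %d samples x %d channels, %d subject(s)\n",
              d[1], d[2], d[3], length(unique(x$subject_id))))
  if (d[1] > 0) print(table(x$label))
  invisible(x)
}

#' Subset a window set
#'
#' @param ws A `window_set`.
#' @param idx Integer or logical index over windows.
#' @return The subset `window_set`.
#' @export
subset_windows <- function(ws, idx) {
  stopifnot(inherits(ws, "window_set"))
  ws$x <- ws$x[idx, , , drop = FALSE]
  ws$subject_id <- ws$subject_id[idx]
  ws$label <- ws$label[idx]
  ws$source <- ws$source[idx]
  ws$lineage <- ws$lineage[idx]
  ws
}

#' Augment one window
#'
#' Training-time augmentation: integer circular shift uniform in
#' `[-shift_max, +shift_max]` samples, additive Gaussian noise, and a
#' multiplicative amplitude scale uniform in `scale_range`. Subject ID and
#' label are inherited unchanged so subject-wise splits remain valid.
#'
#' @param window Numeric matrix (window_len x n_channels) or vector.
#' @param seed Integer seed.
#' @param shift_max Maximum absolute circular shift (samples, default 5).
#' @param noise_sigma Additive noise SD in robust units (default 0.02).
#' @param scale_range Length-2 amplitude-scale range (default c(0.9, 1.1)).
#' @return The augmented window, same shape as the input.
#' @export
augment_window <- function(window, seed, shift_max = 5, noise_sigma = 0.02,
                           scale_range = c(0.9, 1.1)) {
  vec_in <- is.null(dim(window))
  x <- if (vec_in) matrix(window, ncol = 1) else window
  if (shift_max < 0 || noise_sigma < 0 || length(scale_range) != 2 ||
      scale_range[1] > scale_range[2])
    stop("invalid augmentation parameters", call. = FALSE)
  if (nrow(x) <= 2 * shift_max)
    stop("window too short for the requested shift", call. = FALSE)
  out <- with_seed(seed, {
    shift <- sample.int(2 * shift_max + 1, 1) - shift_max - 1
    scale <- stats::runif(1, scale_range[1], scale_range[2])
    n <- nrow(x)
    idx <- ((seq_len(n) - 1 - shift) %% n) + 1
    y <- x[idx, , drop = FALSE] * scale
    if (noise_sigma > 0)
      y <- y + matrix(stats::rnorm(length(y), 0, noise_sigma), nrow(y))
    y
  })
  if (vec_in) as.numeric(out) else out
}

#' Augment a window set
#'
#' Appends `n_copies` augmented copies of each window; augmented windows
#' inherit the source window's subject ID and label and are marked in the
#' lineage, so grouped cross-validation can keep them with their subject.
#'
#' @param ws A `window_set`.
#' @param seed Integer seed (per-window seeds are derived from it).
#' @param n_copies Augmented copies per window (default 1).
#' @param ... Passed to [augment_window()].
#' @return The enlarged `window_set`.
#' @export
augment_window_set <- function(ws, seed, n_copies = 1, ...) {
  stopifnot(inherits(ws, "window_set"))
  k <- dim(ws$x)[1]
  if (k == 0 || n_copies == 0) return(ws)
  pieces <- list(ws)
  for (copy in seq_len(n_copies)) {
    aug <- ws
    for (i in seq_len(k))
      aug$x[i, , ] <- augment_window(ws$x[i, , ],
                                     derive_seed(seed, paste(copy, i)), ...)
    aug$lineage <- rep(sprintf("augmented_%d", copy), k)
    pieces[[copy + 1]] <- aug
  }
  bind_windows(pieces)
}
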