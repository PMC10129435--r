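#' Multi-channel EMG recording
#'
#' Thin validated container for a raw surface-EMG recording: a samples-by-
#' channels matrix of signed amplitudes plus sampling rate and unique channel
#' labels.
#'
#' @param samples numeric matrix, one row per sample, one column per channel.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique muscle names, one per
#'   column (defaults to `colnames(samples)`).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate, channel_labels = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stopf("a recording needs at least 2 samples")
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    stopf("sampling_rate must be positive")
  }
  channel_labels <- channel_labels %||% colnames(samples) %||%
    paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples)) {
    stopf("channel_labels length (%d) must match channel count (%d)",
          length(channel_labels), ncol(samples))
  }
  if (anyDuplicated(channel_labels)) stopf("channel_labels must be unique")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = channel_labels),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d samples x %d channels at %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject normalized gait-cycle matrix
#'
#' The end product of preprocessing: a nonnegative `n_points` by `n_muscles`
#' matrix of envelope amplitudes expressed as fractions of each muscle's
#' per-cycle maximum, time-normalized so rows span 0-100% of the gait cycle.
#'
#' @param values nonnegative numeric matrix.
#' @param channel_labels muscle names, one per column.
#' @param normalized logical; if `TRUE` (the default for preprocessing
#'   output), values must lie in `[0, 1]` and each column must attain 1.
#' @param provenance optional list of processing parameters carried along.
#' @return An object of class `gait_cycle_matrix` (also a plain matrix).
#' @export
gait_cycle_matrix <- function(values, channel_labels = NULL, normalized = TRUE,
                              provenance = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("gait-cycle matrix must be finite and nonnegative")
  }
  channel_labels <- channel_labels %||% colnames(values) %||%
    paste0("ch", seq_len(ncol(values)))
  colnames(values) <- channel_labels
  if (normalized) {
    if (any(values > 1 + 1e-9)) stopf("normalized values must lie in [0, 1]")
    cm <- apply(values, 2L, max)
    if (any(cm < 1 - 1e-6)) {
      stopf("every column of a normalized matrix must attain 1 (worst: %s)",
            channel_labels[which.min(cm)])
    }
  }
  structure(values, class = c("gait_cycle_matrix", "matrix", "array"),
            channel_labels = channel_labels, normalized = normalized,
            provenance = provenance)
}

#' @export
print.gait_cycle_matrix <- function(x, ...) {
  cat(sprintf("Gait-cycle matrix: %d points x %d muscles (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw scale"))
  print(utils::head(unclass(x), 3))
  cat("  ...\n")
  invisible(x)
}

min_filter_length <- function(order) 3L * (order + 1L)

# Zero-phase filtering with odd-symmetric reflection padding and steady-state
# initial conditions, so edge transients do not leak into the first and last
# gait cycles (burst timing near the cycle boundary is an analysis target).
zero_phase_filter <- function(flt, x) {
  b <- flt$b; a <- flt$a
  nf <- max(length(a), length(b))
  n <- length(x)
  p <- min(n - 1L, 12L * (nf - 1L))
  g0 <- sum(b) / sum(a)  # DC gain, for constant-signal steady state
  one_pass <- function(s) {
    as.numeric(signal::filter(flt, s, init.x = rep(s[1L], nf - 1L),
                              init.y = rep(s[1L] * g0, nf - 1L)))
  }
  xp <- c(2 * x[1L] - x[seq(p + 1L, 2L)], x,
          2 * x[n] - x[seq(n - 1L, n - p)])
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(p + 1L):(p + n)]
}

apply_filtfilt <- function(rec, flt, order, stage) {
  n <- nrow(rec$samples)
  need <- min_filter_length(order)
  if (n < need) {
    stopf("%s: recording has %d samples but zero-phase filtering of order %d needs at least %d",
          stage, n, order, need)
  }
  out <- apply(rec$samples, 2L, function(x) zero_phase_filter(flt, x))
  emg_recording(out, rec$sampling_rate, rec$channel_labels)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel. Zero-phase filtering is used throughout because the timing of
#' synergy activation bursts is itself an analysis target and a causal filter
#' would lag it. If `high_hz` reaches the Nyquist frequency the upper edge is
#' clipped to 0.99 x Nyquist with a warning (a 10-500 Hz band at 1000 Hz
#' sampling is nominally degenerate at the upper edge).
#'
#' @param rec an `emg_recording`.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Butterworth order (default 4).
#' @return A filtered `emg_recording` of identical length.
#' @export
bandpass_filter <- function(rec, low_hz = 10, high_hz = 500, order = 4L) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stopf("band edges must satisfy 0 < low_hz < high_hz (got %g, %g)",
          low_hz, high_hz)
  }
  if (high_hz >= nyq) {
    warnf("band upper edge %g Hz >= Nyquist (%g Hz); clipping to %g Hz",
          high_hz, nyq, 0.99 * nyq)
    high_hz <- 0.99 * nyq
    if (low_hz >= high_hz) stopf("band is empty after Nyquist clipping")
  }
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  apply_filtfilt(rec, flt, order, "bandpass_filter")
}

#' Full-wave rectification
#'
#' @param rec an `emg_recording`.
#' @return The element-wise absolute value, as an `emg_recording`.
#' @export
full_wave_rectify <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  emg_recording(abs(rec$samples), rec$sampling_rate, rec$channel_labels)
}

#' Linear-envelope low-pass filter
#'
#' Zero-phase Butterworth low-pass applied per channel to rectified EMG,
#' yielding the linear envelope. Small negative ringing values are clipped to
#' zero.
#'
#' @param rec an `emg_recording` (typically rectified).
#' @param cutoff_hz cutoff frequency in Hz (default 6).
#' @param order Butterworth order (default 4).
#' @return An `emg_recording` holding the nonnegative envelope.
#' @export
lowpass_envelope <- function(rec, cutoff_hz = 6, order = 4L) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) {
    stopf("cutoff must lie in (0, Nyquist) = (0, %g)", nyq)
  }
  flt <- signal::butter(order, cutoff_hz / nyq, type = "low")
  out <- apply_filtfilt(rec, flt, order, "lowpass_envelope")
  out$samples <- pmax(out$samples, 0)
  out
}

check_events <- function(events, n_samples) {
  ev <- as.data.frame(events)
  if (!all(c("start_sample", "end_sample") %in% names(ev))) {
    # allow two-column unnamed input
    if (ncol(ev) >= 2L) {
      names(ev)[1:2] <- c("start_sample", "end_sample")
    } else stopf("events need start_sample and end_sample columns")
  }
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_sample[i]; e <- ev$end_sample[i]
    if (s < 0 || e > n_samples) {
      stopf("cycle %d: event [%d, %d) outside recording of %d samples",
            i, s, e, n_samples)
    }
    if (s >= e) stopf("cycle %d: start %d must precede end %d", i, s, e)
    if (i > 1L && s < ev$end_sample[i - 1L]) {
      stopf("cycle %d overlaps cycle %d", i, i - 1L)
    }
  }
  ev
}

#' Cut a recording into gait cycles
#'
#' Events are 0-based half-open sample intervals `[start, end)`, assumed
#' supplied by external gait-event detection (the pipeline takes events as
#' input rather than detecting them).
#'
#' @param rec an `emg_recording`.
#' @param events data frame (or 2-column matrix) of `start_sample`,
#'   `end_sample`; must be in order, within bounds, non-overlapping.
#' @return List of per-cycle numeric matrices, in event order.
#' @export
segment_cycles <- function(rec, events) {
  stopifnot(inherits(rec, "emg_recording"))
  ev <- check_events(events, nrow(rec$samples))
  lapply(seq_len(nrow(ev)), function(i) {
    rec$samples[(ev$start_sample[i] + 1L):ev$end_sample[i], , drop = FALSE]
  })
}

#' Submaximal amplitude normalization within one cycle
#'
#' Divides each channel by its own maximum within the cycle, so amplitudes
#' become fractions of the per-cycle peak (the submaximal method; no MVC
#' reference is needed).
#'
#' @param cycle nonnegative numeric matrix (samples x channels).
#' @return Matrix with per-channel maximum exactly 1.
#' @export
normalize_amplitude_per_cycle <- function(cycle) {
  cycle <- as.matrix(cycle)
  if (any(cycle < 0)) stopf("cycle must be nonnegative (rectify first)")
  cm <- apply(cycle, 2L, max)
  zero <- which(cm == 0)
  if (length(zero)) {
    lbl <- colnames(cycle)[zero] %||% as.character(zero)
    stopf("channel(s) %s are all zero in this cycle; normalization undefined",
          paste(lbl, collapse = ", "))
  }
  sweep(cycle, 2L, cm, "/")
}

#' Time normalization onto a fixed cycle grid
#'
#' Resamples each channel by natural cubic-spline interpolation onto
#' `n_points` equally spaced positions spanning the whole cycle, endpoints
#' included (point 1 = 0% of the cycle, point `n_points` = 100%). Negative
#' interpolation overshoot is clipped to zero.
#'
#' @param cycle numeric matrix with at least 4 rows.
#' @param n_points grid size (default 101, i.e. 0-100% in 1% steps).
#' @return `n_points` x channels matrix.
#' @export
time_normalize <- function(cycle, n_points = 101L) {
  cycle <- as.matrix(cycle)
  if (nrow(cycle) < 4L) {
    stopf("cubic time normalization needs >= 4 samples per cycle (got %d)",
          nrow(cycle))
  }
  if (!is_count(n_points, 2L)) stopf("n_points must be an integer >= 2")
  x_in <- seq(0, 1, length.out = nrow(cycle))
  x_out <- seq(0, 1, length.out = n_points)
  out <- apply(cycle, 2L, function(y) {
    stats::spline(x_in, y, xout = x_out, method = "natural")$y
  })
  pmax(out, 0)
}

#' Average time-normalized cycles into a subject matrix
#'
#' Element-wise mean across cycles; because averaging per-cycle-normalized
#' envelopes can leave column maxima below 1, each column is re-divided by its
#' own maximum so the matrix keeps the documented 0-1 range with per-muscle
#' maximum exactly 1.
#'
#' @param cycles list of equal-shape `n_points` x `n_muscles` matrices.
#' @param channel_labels optional muscle names.
#' @return A normalized [gait_cycle_matrix()].
#' @export
build_subject_matrix <- function(cycles, channel_labels = NULL) {
  if (length(cycles) < 1L) stopf("need at least one cycle")
  dims <- dim(cycles[[1L]])
  for (i in seq_along(cycles)) {
    if (!identical(dim(cycles[[i]]), dims)) {
      stopf("cycle %d has shape %s; expected %s", i,
            paste(dim(cycles[[i]]), collapse = "x"),
            paste(dims, collapse = "x"))
    }
  }
  avg <- Reduce(`+`, cycles) / length(cycles)
  cm <- apply(avg, 2L, max)
  if (any(cm == 0)) stopf("averaged matrix has an all-zero column")
  avg <- sweep(avg, 2L, cm, "/")
  gait_cycle_matrix(avg, channel_labels %||% colnames(cycles[[1L]]),
                    normalized = TRUE)
}

#' Full preprocessing chain: raw EMG to normalized gait-cycle matrix
#'
#' Band-pass filter, full-wave rectify, low-pass envelope, segment into
#' cycles, normalize amplitude per cycle, time-normalize each cycle, and
#' average across cycles. All stage parameters are recorded in the result's
#' `provenance` attribute.
#'
#' @param rec an `emg_recording`.
#' @param events gait-cycle events (see [segment_cycles()]); must be
#'   non-empty.
#' @param n_points time-normalization grid (default 101).
#' @param band two-element band-pass edges in Hz (default `c(10, 500)`; the
#'   upper edge is Nyquist-clipped with a warning when needed).
#' @param band_order,envelope_order Butterworth orders (default 4).
#' @param envelope_cutoff envelope low-pass cutoff in Hz (default 6).
#' @return A normalized [gait_cycle_matrix()] (`n_points` x `n_channels`).
#' @export
preprocess <- function(rec, events, n_points = 101L, band = c(10, 500),
                       band_order = 4L, envelope_cutoff = 6,
                       envelope_order = 4L) {
  stopifnot(inherits(rec, "emg_recording"))
  if (NROW(events) == 0L) stopf("preprocess: event list is empty")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("preprocess [%s]: %s", name, conditionMessage(e))
    })
  }
  filtered <- stage("bandpass", bandpass_filter(rec, band[1], band[2], band_order))
  rectified <- stage("rectify", full_wave_rectify(filtered))
  envel <- stage("envelope", lowpass_envelope(rectified, envelope_cutoff,
                                              envelope_order))
  cycles <- stage("segment", segment_cycles(envel, events))
  norm <- stage("normalize", lapply(cycles, normalize_amplitude_per_cycle))
  tn <- stage("time_normalize", lapply(norm, time_normalize, n_points = n_points))
  m <- stage("average", build_subject_matrix(tn, rec$channel_labels))
  attr(m, "provenance") <- list(
    band = band, band_order = band_order, envelope_cutoff = envelope_cutoff,
    envelope_order = envelope_order, n_points = n_points,
    n_cycles = length(cycles), sampling_rate = rec$sampling_rate,
    renormalized_after_averaging = TRUE
  )
  m
}
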