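# Plain-text I/O: CSV for recordings, events and matrices; JSON for
# metadata, ground truth and reports; YAML for run configuration.

#' Write / read an EMG recording as CSV
#'
#' One row per sample; columns `time_s` then one column per muscle.
#'
#' @param rec an [emg_recording()].
#' @param path file path.
#' @return `write_emg_csv` returns `path` invisibly; `read_emg_csv` returns
#'   an `emg_recording` (the sampling rate is recovered from the time column).
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- data.frame(time_s = (seq_len(nrow(rec$samples)) - 1L) / rec$sampling_rate)
  df <- cbind(df, as.data.frame(rec$samples))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stopf("%s: missing time_s column", path)
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0)) stopf("%s: time_s must increase", path)
  fs <- 1 / stats::median(dt)
  emg_recording(as.matrix(df[setdiff(names(df), "time_s")]), fs,
                setdiff(names(df), "time_s"))
}

#' Write / read gait-cycle events as CSV
#'
#' Columns `cycle_index`, `start_sample`, `end_sample` (0-based, half-open).
#'
#' @param events data frame of events.
#' @param path file path.
#' @export
write_events_csv <- function(events, path) {
  ev <- as.data.frame(events)[, c("cycle_index", "start_sample", "end_sample")]
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a gait-cycle matrix as CSV with a JSON provenance sidecar
#'
#' @param m a [gait_cycle_matrix()] (or plain matrix).
#' @param path CSV path; provenance, if present, goes to `<path>.json`.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(as.matrix(m))), path,
                   row.names = FALSE)
  prov <- attr(m, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  gait_cycle_matrix(m, colnames(m), normalized = FALSE)
}

#' Write a synergy decomposition as CSV pair plus JSON metadata
#'
#' `H` goes to `<prefix>_H.csv` (one column per synergy), `W` to
#' `<prefix>_W.csv` (muscle-labeled columns), and metadata (k, VAF, loss,
#' seed, iterations) to `<prefix>_meta.json`.
#'
#' @param dec a `synergy_nmf`.
#' @param prefix path prefix.
#' @export
write_decomposition <- function(dec, prefix) {
  stopifnot(inherits(dec, "synergy_nmf"))
  utils::write.csv(as.data.frame(dec$H), paste0(prefix, "_H.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dec$W), paste0(prefix, "_W.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(k = dec$k, frobenius_loss = dec$frobenius_loss,
         vaf_per_muscle = as.list(dec$vaf_per_muscle),
         vaf_global = dec$vaf_global, seed_used = dec$seed_used,
         n_iterations = dec$n_iterations),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Serialize a ground-truth synergy model as JSON
#'
#' @param model a [synergy_model()].
#' @param path file path.
#' @export
write_ground_truth_json <- function(model, path) {
  stopifnot(inherits(model, "synergy_model"))
  jsonlite::write_json(
    list(k_true = model$k_true, muscles = model$muscles,
         W = apply(model$W, 1L, as.list),
         burst_centers = model$burst_centers,
         burst_widths = model$burst_widths,
         noise_sigma = model$noise_sigma, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a group comparison report as JSON and CSV tables
#'
#' Emits `report.json` plus CSVs mirroring the usual result tables: VAF by k
#' and group, the k x k correlation matrix with a matched-diagonal flag, and
#' the per-(synergy, muscle) weight table with significance marks.
#'
#' @param report a `synergy_comparison`.
#' @param dir output directory (created if missing).
#' @export
write_comparison_report <- function(report, dir) {
  stopifnot(inherits(report, "synergy_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(groups = report$groups, alpha = report$alpha,
         correlation_matrix = report$correlation_matrix,
         similarity_class = report$similarity_class,
         matched_pairs = report$matched_pairs,
         weight_tests = report$weight_tests,
         vaf_tests = report$vaf_tests),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, matrix = "rowmajor")
  cm <- as.data.frame(report$correlation_matrix)
  cm <- cbind(synergy_A = rownames(report$correlation_matrix), cm)
  cm$matched <- seq_len(nrow(cm)) <= ncol(report$correlation_matrix)
  utils::write.csv(cm, file.path(dir, "correlation_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(report$weight_tests, file.path(dir, "weight_tests.csv"),
                   row.names = FALSE)
  if (!is.null(report$vaf_tests)) {
    utils::write.csv(report$vaf_tests, file.path(dir, "vaf_tests.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
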