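# End-to-end orchestration: simulate (or load) a cohort, preprocess every
# subject, select synergy counts, harmonize k within groups, and compare
# groups — one deterministic run from a single config.

#' Default pipeline configuration
#'
#' All values mirror the analysis defaults: 101-point cycles, 10-500 Hz
#' band-pass, 6 Hz envelope, per-muscle VAF threshold 0.9, alpha 0.05.
#'
#' @param seed master seed; every random draw in the run descends from it.
#' @return Nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      enabled = TRUE,
      noise_sigma = 0.2,
      n_subjects = 10L,
      n_cycles_per_subject = 3L,
      weight_jitter_sd = 0.1,
      weight_perturbations = NULL
    ),
    input_dir = NULL,
    preprocess = list(n_points = 101L, band = c(10, 500), band_order = 4L,
                      envelope_cutoff = 6, envelope_order = 4L),
    extract = list(threshold = 0.9, k_max = 5L, n_restarts = 20L,
                   max_iter = 2000L, tol = 1e-6),
    compare = list(alpha = 0.05, correction = "none", nonparametric = FALSE)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config(y$seed %||% 1L)
  merge_section <- function(section) {
    for (nm in names(y[[section]])) {
      if (!nm %in% names(cfg[[section]])) {
        stopf("unknown config field %s.%s", section, nm)
      }
      cfg[[section]][[nm]] <<- y[[section]][[nm]]
    }
  }
  for (s in intersect(c("simulate", "preprocess", "extract", "compare"),
                      names(y))) {
    merge_section(s)
  }
  if (!is.null(y$input_dir)) cfg$input_dir <- y$input_dir
  unknown <- setdiff(names(y), c("seed", "input_dir", "simulate", "preprocess",
                                 "extract", "compare"))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every numeric parameter against the preconditions of the stage that
#' consumes it. Never throws; returns a character vector of violations,
#' empty when the configuration is valid.
#'
#' @param config a `run_config` (or compatible list).
#' @return Character vector of human-readable violations.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(is_count(config$seed %||% NA, 0L) || is_number(config$seed),
      "seed must be an integer")
  p <- config$preprocess
  chk(is_count(p$n_points %||% NA, 2L), "preprocess.n_points must be an integer >= 2")
  chk(length(p$band) == 2L && p$band[1] > 0 && p$band[1] < p$band[2],
      "preprocess.band must satisfy 0 < low < high")
  chk(is_count(p$band_order %||% NA, 1L), "preprocess.band_order must be >= 1")
  chk(is_number(p$envelope_cutoff %||% NA) && p$envelope_cutoff > 0,
      "preprocess.envelope_cutoff must be > 0")
  e <- config$extract
  chk(is_number(e$threshold %||% NA) && e$threshold > 0 && e$threshold < 1,
      "extract.threshold must lie in (0, 1)")
  chk(is_count(e$k_max %||% NA, 1L), "extract.k_max must be an integer >= 1")
  chk(is_count(e$n_restarts %||% NA, 1L), "extract.n_restarts must be >= 1")
  chk(is_count(e$max_iter %||% NA, 1L), "extract.max_iter must be >= 1")
  chk(is_number(e$tol %||% NA) && e$tol > 0, "extract.tol must be > 0")
  cc <- config$compare
  chk(is_number(cc$alpha %||% NA) && cc$alpha > 0 && cc$alpha < 1,
      "compare.alpha must lie in (0, 1)")
  chk((cc$correction %||% "none") %in% c("none", "holm"),
      "compare.correction must be 'none' or 'holm'")
  if (isTRUE(config$simulate$enabled)) {
    s <- config$simulate
    chk(is_count(s$n_subjects %||% NA, 2L), "simulate.n_subjects must be an integer >= 2")
    chk(is_count(s$n_cycles_per_subject %||% NA, 1L),
        "simulate.n_cycles_per_subject must be >= 1")
    chk(is_number(s$noise_sigma %||% NA) && s$noise_sigma >= 0,
        "simulate.noise_sigma must be >= 0")
    chk(is_number(s$weight_jitter_sd %||% NA) && s$weight_jitter_sd >= 0,
        "simulate.weight_jitter_sd must be >= 0")
  } else {
    chk(!is.null(config$input_dir) && dir.exists(config$input_dir),
        "input_dir must exist when simulation is disabled")
  }
  v
}

modal_k <- function(ks) {
  tab <- table(ks)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)  # ties go to the smaller synergy count
}

load_cohort_dir <- function(input_dir) {
  # expects <input_dir>/<group>/<subject>_emg.csv + <subject>_events.csv
  groups <- list()
  for (g in c("A", "B")) {
    gd <- file.path(input_dir, g)
    if (!dir.exists(gd)) stopf("missing group directory %s", gd)
    emg_files <- sort(list.files(gd, "_emg\\.csv$", full.names = TRUE))
    if (length(emg_files) == 0L) stopf("no *_emg.csv files in %s", gd)
    subjects <- lapply(emg_files, function(f) {
      id <- sub("_emg\\.csv$", "", basename(f))
      ev <- sub("_emg\\.csv$", "_events.csv", f)
      if (!file.exists(ev)) stopf("missing events file %s", ev)
      list(id = id, group = g, recording = read_emg_csv(f),
           events = read_events_csv(ev))
    })
    names(subjects) <- vapply(subjects, `[[`, "", "id")
    groups[[g]] <- subjects
  }
  groups
}

#' Run the full synergy pipeline
#'
#' simulate (or load) -> preprocess -> select synergy count per subject ->
#' re-fit stragglers at each group's modal k -> group means -> two-group
#' comparison. Deterministic given the config: all randomness is seeded from
#' `config$seed`. When `out_dir` is given, per-subject matrices and
#' decompositions, the group report and a run manifest are written there; the
#' run is first assembled in a temporary directory and atomically renamed, so
#' a failed run leaves no partial output.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir optional output directory.
#' @param model optional [synergy_model()] overriding the default ground
#'   truth when simulating.
#' @return An object of class `synergy_run`: list with `subjects` (per-subject
#'   id, group, matrix, selection curve, decomposition at the group k),
#'   `group_sets`, `report`, `modal_k`, `config`, `warnings`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         model = NULL) {
  violations <- validate_config(config)
  if (length(violations)) {
    stopf("invalid configuration:\n- %s", paste(violations, collapse = "\n- "))
  }
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    s <- config$simulate
    model <- model %||% default_synergy_model(noise_sigma = s$noise_sigma,
                                              seed = config$seed)
    spec <- cohort_spec(
      n_subjects = s$n_subjects,
      n_cycles_per_subject = s$n_cycles_per_subject,
      weight_perturbations = s$weight_perturbations,
      weight_jitter_sd = s$weight_jitter_sd
    )
    cohort <- generate_cohort(model, spec, level = "raw")
    groups_in <- cohort$groups
  } else {
    cohort <- NULL
    groups_in <- load_cohort_dir(config$input_dir)
  }

  # --- per-subject preprocessing and synergy-count selection --------------
  p <- config$preprocess; e <- config$extract
  subjects <- list()
  for (g in names(groups_in)) {
    for (sub in groups_in[[g]]) {
      m <- collect(preprocess(sub$recording, sub$events,
                              n_points = p$n_points, band = p$band,
                              band_order = p$band_order,
                              envelope_cutoff = p$envelope_cutoff,
                              envelope_order = p$envelope_order))
      curve <- collect(select_num_synergies(
        m, threshold = e$threshold, k_max = e$k_max,
        seed = derive_seed(config$seed, length(subjects) + 1L),
        n_restarts = e$n_restarts, max_iter = e$max_iter, tol = e$tol))
      subjects[[sub$id]] <- list(id = sub$id, group = g, matrix = m,
                                 curve = curve,
                                 k_selected = curve$k_selected)
    }
  }

  # --- harmonize k and build group sets -----------------------------------
  # each group's modal selected k is reported; the comparison itself needs a
  # common k across groups, so if the modal values differ the overall modal
  # k is used for both and the divergence is surfaced as a warning
  group_modal <- vapply(names(groups_in), function(g) {
    modal_k(vapply(Filter(function(x) x$group == g, subjects), `[[`, 0L,
                   "k_selected"))
  }, 0L)
  k_common <- modal_k(vapply(subjects, `[[`, 0L, "k_selected"))
  if (length(unique(group_modal)) > 1L) {
    warnings_seen <- c(warnings_seen, sprintf(
      "groups selected different modal k (%s); comparison run at overall modal k = %d",
      paste(sprintf("%s:%d", names(group_modal), group_modal), collapse = ", "),
      k_common))
  }
  group_sets <- list()
  vaf_lists <- list()
  for (g in names(groups_in)) {
    gs <- Filter(function(x) x$group == g, subjects)
    k_g <- k_common
    decs <- lapply(gs, function(x) {
      if (length(x$curve$per_k) >= k_g && !is.null(x$curve$per_k[[k_g]])) {
        x$curve$per_k[[k_g]]
      } else {
        # selection stopped before reaching the group k; fit it now
        collect(nnmf_decompose(x$matrix, k_g,
                               seed = derive_seed(config$seed, 500L + k_g),
                               n_restarts = e$n_restarts,
                               max_iter = e$max_iter, tol = e$tol))
      }
    })
    refit <- vapply(gs, function(x) x$k_selected != k_g, TRUE)
    if (any(refit)) {
      warnings_seen <- c(warnings_seen, sprintf(
        "group %s: subject(s) %s selected k != modal k = %d and were re-fitted",
        g, paste(names(gs)[refit], collapse = ", "), k_g))
    }
    for (i in seq_along(gs)) {
      subjects[[names(gs)[i]]]$decomposition <- decs[[i]]
      subjects[[names(gs)[i]]]$refit_at_modal_k <- refit[i]
    }
    group_sets[[g]] <- group_mean_synergies(unname(decs), group_label = g)
    # per-subject global VAF at every k reached by each subject's curve
    kk_all <- sort(unique(unlist(lapply(gs, function(x) x$curve$vaf_table$k))))
    vaf_lists[[g]] <- lapply(stats::setNames(kk_all, kk_all), function(kk) {
      unlist(lapply(gs, function(x) {
        vt <- x$curve$vaf_table
        vt$vaf_global[match(kk, vt$k)]
      }))
    })
    vaf_lists[[g]] <- Filter(function(x) sum(!is.na(x)) >= 2L, vaf_lists[[g]])
  }

  # --- comparison ---------------------------------------------------------
  cc <- config$compare
  report <- collect(compare_groups(
    group_sets[[1L]], group_sets[[2L]], alpha = cc$alpha,
    vafsA = lapply(vaf_lists[[1L]], function(x) x[!is.na(x)]),
    vafsB = lapply(vaf_lists[[2L]], function(x) x[!is.na(x)]),
    correction = cc$correction, nonparametric = cc$nonparametric))

  run <- structure(
    list(subjects = subjects, group_sets = group_sets, report = report,
         modal_k = group_modal, k_common = k_common,
         config = config, cohort = cohort, warnings = warnings_seen),
    class = "synergy_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  parent <- dirname(out_dir)
  if (!dir.exists(parent)) dir.create(parent, recursive = TRUE)
  tmp <- tempfile("synergy_run_", tmpdir = parent)
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE), add = TRUE)
  for (sub in run$subjects) {
    pre <- file.path(tmp, sub$id)
    write_matrix_csv(sub$matrix, paste0(pre, "_matrix.csv"))
    write_decomposition(sub$decomposition, pre)
    utils::write.csv(sub$curve$vaf_table, paste0(pre, "_vaf_curve.csv"),
                     row.names = FALSE)
  }
  write_comparison_report(run$report, file.path(tmp, "report"))
  files <- sort(list.files(tmp, recursive = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitsynergy")),
    config = unclass(run$config),
    modal_k = as.list(run$modal_k),
    warnings = run$warnings,
    checksums = as.list(stats::setNames(
      vapply(files, function(f) {
        unname(as.character(tools::md5sum(file.path(tmp, f))))
      }, ""),
      files))
  )
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  ok <- file.rename(tmp, out_dir)
  if (!ok) stopf("failed to move run outputs into %s", out_dir)
  invisible(out_dir)
}

#' @export
print.synergy_run <- function(x, ...) {
  cat(sprintf("Synergy pipeline run: %d subjects, modal k = %s\n",
              length(x$subjects),
              paste(sprintf("%s:%d", names(x$modal_k), x$modal_k),
                    collapse = ", ")))
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s) collected; first: %s\n", length(x$warnings),
                x$warnings[[1L]]))
  }
  print(x$report)
  invisible(x)
}
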