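#' Ground-truth synergy model for synthetic EMG
#'
#' Defines the generative model used by the synthetic cohort generator: a set
#' of `k_true` muscle synergies, each a nonnegative weight vector over muscles
#' (`W`) driven by a Gaussian activation burst at a fixed position in the gait
#' cycle. Raw-EMG-like signals are synthesized by amplitude-modulating
#' band-limited carrier noise with the resulting envelope, so the full
#' preprocessing and factorization pipeline can be validated by parameter
#' recovery.
#'
#' @param W nonnegative matrix, `k_true` rows (synergies) by `n_muscles`
#'   columns. Each row is rescaled so its maximum entry is 1 (canonical
#'   scale). Column names, if present, are used as muscle labels.
#' @param burst_centers numeric vector of length `k_true`; activation-peak
#'   position of each synergy in percent of the gait cycle (0-100). Must be
#'   distinct (recovery tests need identifiable components).
#' @param burst_widths numeric vector (recycled) of Gaussian burst standard
#'   deviations, in percent of cycle.
#' @param noise_sigma relative scale of multiplicative log-normal envelope
#'   noise (0 = noiseless).
#' @param seed integer seed governing all randomness derived from this model.
#' @param muscles character vector of muscle labels (defaults to `colnames(W)`
#'   or M1..Mn).
#' @return An object of class `synergy_model`.
#' @seealso [default_synergy_model()], [generate_cohort()]
#' @export
synergy_model <- function(W, burst_centers, burst_widths, noise_sigma = 0.2,
                          seed = 1L, muscles = NULL) {
  W <- as.matrix(W)
  if (any(!is.finite(W)) || any(W < 0)) {
    stopf("W must be a finite nonnegative matrix")
  }
  k <- nrow(W)
  if (k < 1L) stopf("W needs at least one row (k_true >= 1)")
  if (length(burst_centers) != k) {
    stopf("burst_centers must have one entry per synergy (%d)", k)
  }
  if (any(burst_centers < 0 | burst_centers > 100)) {
    stopf("burst_centers must lie in [0, 100]")
  }
  if (anyDuplicated(burst_centers)) {
    stopf("burst_centers must be distinct")
  }
  burst_widths <- rep_len(burst_widths, k)
  if (any(burst_widths <= 0)) stopf("burst_widths must be positive")
  if (!is_number(noise_sigma) || noise_sigma < 0) {
    stopf("noise_sigma must be a nonnegative number")
  }
  row_max <- apply(W, 1L, max)
  if (any(row_max == 0)) stopf("every synergy must weight at least one muscle")
  W <- W / row_max  # canonical scale: each row has max 1
  muscles <- muscles %||% colnames(W) %||% paste0("M", seq_len(ncol(W)))
  colnames(W) <- muscles
  structure(
    list(k_true = k, W = W, burst_centers = as.numeric(burst_centers),
         burst_widths = as.numeric(burst_widths),
         noise_sigma = noise_sigma, seed = as.integer(seed),
         muscles = muscles),
    class = "synergy_model"
  )
}

#' Default four-synergy walking model
#'
#' A five-muscle (GA, TA, VL, GM, BF), four-synergy ground truth emulating the
#' canonical modular organization of human walking: weight acceptance in early
#' stance (hip/knee extensors), plantarflexor push-off mid-cycle, dorsiflexor
#' activity in early swing, and hamstring-dominated deceleration in late
#' swing. Burst positions are 12, 45, 70 and 92 percent of the cycle.
#'
#' @param noise_sigma envelope noise scale (default 0.2, a moderate level for
#'   surface EMG envelopes).
#' @param seed integer seed.
#' @return A `synergy_model`.
#' @export
default_synergy_model <- function(noise_sigma = 0.2, seed = 1L) {
  muscles <- c("GA", "TA", "VL", "GM", "BF")
  W <- rbind(
    c(0.05, 0.10, 0.45, 1.00, 0.20),  # weight acceptance, early stance
    c(1.00, 0.05, 0.10, 0.10, 0.05),  # plantarflexor push-off
    c(0.05, 1.00, 0.10, 0.05, 0.10),  # dorsiflexion, early swing
    c(0.10, 0.20, 0.75, 0.35, 1.00)   # late-swing deceleration
  )
  colnames(W) <- muscles
  synergy_model(W, burst_centers = c(12, 45, 70, 92),
                burst_widths = c(9, 8, 8, 7),
                noise_sigma = noise_sigma, seed = seed, muscles = muscles)
}

#' Cohort design for synthetic two-group studies
#'
#' @param n_subjects subjects per group (>= 2).
#' @param n_cycles_per_subject gait cycles recorded per subject (default 3,
#'   one per walking repetition).
#' @param weight_perturbations `NULL` or a data frame with columns `group`,
#'   `synergy`, `muscle`, `factor`: multiplicative factors (> 0) applied to
#'   the named ground-truth weight entries for that group's subjects.
#' @param sampling_rate sampling rate of the synthesized raw EMG, in Hz.
#' @param cycle_duration_mean,cycle_duration_sd mean and SD (seconds) of the
#'   simulated gait-cycle duration.
#' @param weight_jitter_sd SD of the multiplicative between-subject jitter on
#'   weight entries (truncated below at 0); gives groups within-group
#'   variance.
#' @param carrier_band two-element numeric; band (Hz) of the Gaussian carrier
#'   noise that the envelope amplitude-modulates.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, n_cycles_per_subject = 3L,
                        weight_perturbations = NULL, sampling_rate = 1000,
                        cycle_duration_mean = 1.1, cycle_duration_sd = 0.08,
                        weight_jitter_sd = 0.1, carrier_band = c(20, 450)) {
  if (!is_count(n_subjects, 2L)) stopf("n_subjects must be an integer >= 2")
  if (!is_count(n_cycles_per_subject, 1L)) {
    stopf("n_cycles_per_subject must be an integer >= 1")
  }
  if (!is.null(weight_perturbations)) {
    wp <- as.data.frame(weight_perturbations)
    need <- c("group", "synergy", "muscle", "factor")
    if (!all(need %in% names(wp))) {
      stopf("weight_perturbations needs columns %s", paste(need, collapse = ", "))
    }
    if (any(wp$factor <= 0)) stopf("perturbation factors must be > 0")
    weight_perturbations <- wp
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    stopf("sampling_rate must be positive")
  }
  if (!is_number(cycle_duration_mean) || cycle_duration_mean <= 0) {
    stopf("cycle_duration_mean must be > 0")
  }
  if (cycle_duration_sd < 0) stopf("cycle_duration_sd must be >= 0")
  if (weight_jitter_sd < 0) stopf("weight_jitter_sd must be >= 0")
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[1] >= carrier_band[2]) {
    stopf("carrier_band must be increasing and positive")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_cycles_per_subject = as.integer(n_cycles_per_subject),
         weight_perturbations = weight_perturbations,
         sampling_rate = sampling_rate,
         cycle_duration_mean = cycle_duration_mean,
         cycle_duration_sd = cycle_duration_sd,
         weight_jitter_sd = weight_jitter_sd,
         carrier_band = as.numeric(carrier_band)),
    class = "cohort_spec"
  )
}

#' Ground-truth synergy activation profiles
#'
#' Realizes the activation-coefficient matrix H of the generative model as one
#' Gaussian burst per synergy, peak value 1, evaluated on a circular cycle
#' domain (0% and 100% are the same gait event, so bursts near the cycle
#' boundary wrap around).
#'
#' @param model a `synergy_model`.
#' @param n_points number of equally spaced samples spanning 0-100% of the
#'   cycle, endpoints included (default 101).
#' @return Nonnegative matrix, `n_points` rows by `k_true` columns.
#' @export
make_activation_profiles <- function(model, n_points = 101L) {
  stopifnot(inherits(model, "synergy_model"))
  if (!is_count(n_points, 2L)) stopf("n_points must be an integer >= 2")
  pct <- seq(0, 100, length.out = n_points)
  H <- vapply(seq_len(model$k_true), function(j) {
    d <- abs(pct - model$burst_centers[j])
    d <- pmin(d, 100 - d)  # circular distance on the cycle
    exp(-d^2 / (2 * model$burst_widths[j]^2))
  }, numeric(n_points))
  colnames(H) <- paste0("S", seq_len(model$k_true))
  H
}

#' Synthesize a noisy envelope matrix from the generative model
#'
#' Runs the synergy model forward: `H_true %*% W_true`, optionally corrupted
#' by multiplicative log-normal noise of scale `noise_sigma` (mean 1), clipped
#' at zero. With `noise_sigma = 0` the product is returned exactly.
#'
#' @param model a `synergy_model`; set `W` to override the model's weights
#'   (e.g. a jittered per-subject matrix).
#' @param n_points samples per cycle (default 101).
#' @param seed RNG seed for the noise draw (default: the model's seed).
#' @param W optional replacement weight matrix (same shape as `model$W`).
#' @return Nonnegative `n_points` by `n_muscles` matrix with muscle column
#'   names.
#' @export
synthesize_envelope <- function(model, n_points = 101L, seed = model$seed,
                                W = NULL) {
  stopifnot(inherits(model, "synergy_model"))
  W <- W %||% model$W
  H <- make_activation_profiles(model, n_points)
  E <- H %*% W
  if (model$noise_sigma > 0) {
    sig <- model$noise_sigma
    E <- with_seed(seed, {
      E * matrix(stats::rlnorm(length(E), meanlog = -sig^2 / 2, sdlog = sig),
                 nrow(E), ncol(E))
    })
  }
  E <- pmax(E, 0)
  colnames(E) <- model$muscles
  E
}

#' Synthesize a raw EMG recording for one subject
#'
#' Each muscle channel is zero-mean band-limited Gaussian carrier noise
#' amplitude-modulated by the subject's target envelope, resampled from cycle
#' percent onto real time at `sampling_rate`. Gait cycles have seeded random
#' durations; exact cycle boundaries are returned as 0-based half-open sample
#' intervals, emulating externally supplied gait events.
#'
#' @param model a `synergy_model`.
#' @param spec a `cohort_spec`.
#' @param subject_seed integer seed for this subject's noise and cycle
#'   durations.
#' @param W optional per-subject weight matrix overriding `model$W`.
#' @return A list with elements `recording` (an [emg_recording()]), `events`
#'   (data frame: `cycle_index`, `start_sample`, `end_sample`), and
#'   `envelope_target` (the noiseless 101-point envelope `H %*% W`).
#' @export
synthesize_raw_emg <- function(model, spec, subject_seed, W = NULL) {
  stopifnot(inherits(model, "synergy_model"), inherits(spec, "cohort_spec"))
  fs <- spec$sampling_rate
  if (spec$carrier_band[2] >= fs / 2) {
    stopf("carrier band upper edge must be below Nyquist (%g Hz)", fs / 2)
  }
  W <- W %||% model$W
  H <- make_activation_profiles(model, 101L)
  target <- H %*% W
  colnames(target) <- model$muscles
  pct_grid <- seq(0, 100, length.out = 101L)
  n_mus <- length(model$muscles)

  with_seed(subject_seed, {
    n_cyc <- spec$n_cycles_per_subject
    dur <- stats::rnorm(n_cyc, spec$cycle_duration_mean, spec$cycle_duration_sd)
    dur <- pmax(dur, 0.25 * spec$cycle_duration_mean)
    n_samp <- pmax(4L, as.integer(round(dur * fs)))
    starts <- cumsum(c(0L, n_samp[-n_cyc]))
    total <- sum(n_samp)

    # Per-sample envelope: linear resample of the 101-point target onto each
    # cycle's real-time grid, with multiplicative log-normal noise.
    env <- matrix(0, total, n_mus)
    for (ci in seq_len(n_cyc)) {
      idx <- (starts[ci] + 1L):(starts[ci] + n_samp[ci])
      pct <- seq(0, 100, length.out = n_samp[ci])
      for (m in seq_len(n_mus)) {
        e <- stats::approx(pct_grid, target[, m], xout = pct)$y
        env[idx, m] <- e
      }
    }
    if (model$noise_sigma > 0) {
      sig <- model$noise_sigma
      env <- env * matrix(stats::rlnorm(length(env), -sig^2 / 2, sig),
                          nrow(env), ncol(env))
    }

    # Band-limited unit-variance Gaussian carrier per channel.
    bf <- signal::butter(4, spec$carrier_band / (fs / 2), type = "pass")
    carrier <- vapply(seq_len(n_mus), function(m) {
      x <- signal::filtfilt(bf, stats::rnorm(total))
      x / stats::sd(x)
    }, numeric(total))

    samples <- env * carrier
    events <- data.frame(
      cycle_index = seq_len(n_cyc) - 1L,
      start_sample = starts,
      end_sample = starts + n_samp
    )
    list(
      recording = emg_recording(samples, fs, model$muscles),
      events = events,
      envelope_target = target
    )
  })
}

apply_perturbations <- function(W, perturbations, group, muscles) {
  if (is.null(perturbations)) return(W)
  wp <- perturbations[perturbations$group == group, , drop = FALSE]
  for (i in seq_len(nrow(wp))) {
    s <- wp$synergy[i]
    m <- wp$muscle[i]
    mi <- if (is.character(m)) match(m, muscles) else as.integer(m)
    if (is.na(mi) || mi < 1L || mi > length(muscles)) {
      stopf("unknown muscle '%s' in weight_perturbations", m)
    }
    if (s < 1L || s > nrow(W)) {
      stopf("synergy index %s out of range in weight_perturbations", s)
    }
    W[s, mi] <- W[s, mi] * wp$factor[i]
  }
  W
}

#' Generate a two-group synthetic cohort
#'
#' Builds per-subject recordings for groups "A" and "B" from a shared
#' ground-truth model. Group B subjects use `model$W` with
#' `spec$weight_perturbations` applied; every subject additionally receives
#' small seeded multiplicative jitter on the weight entries so between-subject
#' variance exists. All randomness descends deterministically from
#' `model$seed`.
#'
#' @param model a `synergy_model`.
#' @param spec a `cohort_spec`.
#' @param level `"raw"` synthesizes full raw EMG recordings plus gait events
#'   (exercises the preprocessing chain); `"envelope"` skips carrier synthesis
#'   and returns each subject's noisy 101-point envelope matrix directly
#'   (fast path for Monte-Carlo studies of the factorization and statistics).
#' @return A list with `groups` (named list `A`, `B` of per-subject lists,
#'   each holding the subject's data and its true weight matrix `W_subject`),
#'   `model`, and `spec`.
#' @export
generate_cohort <- function(model, spec, level = c("raw", "envelope")) {
  stopifnot(inherits(model, "synergy_model"), inherits(spec, "cohort_spec"))
  level <- match.arg(level)
  groups <- list()
  for (g in c("A", "B")) {
    W_g <- apply_perturbations(model$W, spec$weight_perturbations, g,
                               model$muscles)
    gi <- match(g, c("A", "B")) - 1L
    subjects <- lapply(seq_len(spec$n_subjects), function(i) {
      seed_i <- derive_seed(model$seed, gi * spec$n_subjects + i)
      W_i <- if (spec$weight_jitter_sd > 0) {
        with_seed(seed_i, {
          jit <- matrix(stats::rnorm(length(W_g), 1, spec$weight_jitter_sd),
                        nrow(W_g), ncol(W_g))
          pmax(W_g * jit, 0)
        })
      } else W_g
      sub <- list(id = sprintf("%s%02d", g, i), group = g, W_subject = W_i,
                  seed = seed_i)
      if (level == "raw") {
        sim <- synthesize_raw_emg(model, spec, derive_seed(seed_i, 1L), W = W_i)
        sub$recording <- sim$recording
        sub$events <- sim$events
        sub$envelope_target <- sim$envelope_target
      } else {
        sub$envelope <- synthesize_envelope(model, 101L,
                                            seed = derive_seed(seed_i, 2L),
                                            W = W_i)
        sub$envelope_target <- make_activation_profiles(model, 101L) %*% W_i
      }
      sub
    })
    names(subjects) <- vapply(subjects, `[[`, "", "id")
    groups[[g]] <- subjects
  }
  list(groups = groups, model = model, spec = spec)
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("Ground-truth synergy model: %d synergies, %d muscles\n",
              x$k_true, length(x$muscles)))
  cat("  burst centers (% cycle):", paste(x$burst_centers, collapse = ", "), "\n")
  cat("  burst widths  (% cycle):", paste(x$burst_widths, collapse = ", "), "\n")
  cat(sprintf("  envelope noise sigma: %g, seed: %d\n", x$noise_sigma, x$seed))
  cat("  W (rows max-1):\n")
  print(round(x$W, 3))
  invisible(x)
}
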