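make_rec <- function(x, fs = 1000) {
  emg_recording(cbind(ch = x), fs)
}

test_that("band-pass attenuates out-of-band and passes in-band tones", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  core <- 500:1500  # away from filtfilt edge transients
  lo <- bandpass_filter(make_rec(sin(2 * pi * 2 * t)), 10, 450)
  expect_lt(sqrt(mean(lo$samples[core, 1]^2)),
            0.05 * sqrt(mean(sin(2 * pi * 2 * t[core])^2)))
  mid <- bandpass_filter(make_rec(sin(2 * pi * 100 * t)), 10, 450)
  expect_equal(sqrt(mean(mid$samples[core, 1]^2)),
               sqrt(mean(sin(2 * pi * 100 * t[core])^2)),
               tolerance = 0.05)
  zero <- bandpass_filter(make_rec(rep(0, 2001)), 10, 450)
  expect_true(all(zero$samples == 0))
})

test_that("band edges at or above Nyquist are clipped with a warning", {
  x <- make_rec(stats::rnorm(2000))
  expect_warning(bandpass_filter(x, 10, 500), "Nyquist")
  expect_warning(y <- bandpass_filter(x, 10, 600), "clipping")
  expect_equal(nrow(y$samples), 2000L)
  expect_error(bandpass_filter(x, 450, 100), "low_hz < high_hz")
})

test_that("too-short recordings fail with the minimum length named", {
  x <- emg_recording(cbind(a = stats::rnorm(8)), 1000)
  expect_error(bandpass_filter(x, 10, 450, order = 4), "at least 15")
})

test_that("filtering is homogeneous of degree one per channel", {
  set.seed(4)
  x <- stats::rnorm(1500)
  a <- 3.7
  f1 <- bandpass_filter(make_rec(a * x), 10, 450)
  f2 <- bandpass_filter(make_rec(x), 10, 450)
  expect_lt(max(abs(f1$samples - a * f2$samples)), 1e-8 * max(abs(f1$samples)))
})

test_that("full-wave rectification is the element-wise absolute value", {
  r <- full_wave_rectify(make_rec(c(-1, 2, -3, 0.5)))
  expect_equal(unname(r$samples[, 1]), c(1, 2, 3, 0.5))
  nn <- make_rec(c(0.1, 0.4, 2))
  expect_identical(full_wave_rectify(nn)$samples, nn$samples)
})

test_that("envelope low-pass has unit DC gain, low ripple, and clips at 0", {
  fs <- 1000
  const <- lowpass_envelope(make_rec(rep(2.5, 1500)), 6)
  expect_equal(unname(const$samples[, 1]), rep(2.5, 1500), tolerance = 1e-6)

  t <- seq(0, 2, by = 1 / fs)
  env <- lowpass_envelope(full_wave_rectify(make_rec(sin(2 * pi * 100 * t))), 6)
  seg <- env$samples[700:1300, 1]
  expect_lt(max(seg) - min(seg), 0.1 * mean(seg))  # ripple < 10% of mean
  expect_gte(min(env$samples), 0)
})

test_that("cycle segmentation honors 0-based half-open events", {
  rec <- emg_recording(matrix(seq_len(2000), 1000, 2), 1000, c("a", "b"))
  cyc <- segment_cycles(rec, data.frame(start_sample = c(0L, 500L),
                                        end_sample = c(500L, 1000L)))
  expect_length(cyc, 2L)
  expect_equal(dim(cyc[[1]]), c(500L, 2L))
  expect_equal(unname(cyc[[1]][1, "a"]), 1)     # sample index 0 is the first row
  expect_equal(unname(cyc[[2]][1, "a"]), 501)   # half-open: cycle 2 starts at 500
  expect_length(segment_cycles(rec, data.frame(start_sample = integer(),
                                               end_sample = integer())), 0L)
  expect_error(segment_cycles(rec, data.frame(start_sample = c(0, 400),
                                              end_sample = c(500, 900))),
               "overlaps")
  expect_error(segment_cycles(rec, data.frame(start_sample = 900,
                                              end_sample = 1100)),
               "outside")
  expect_error(segment_cycles(rec, data.frame(start_sample = 500,
                                              end_sample = 400)),
               "precede")
})

test_that("per-cycle amplitude normalization is exact and idempotent", {
  m <- cbind(a = c(0, 2, 4), b = c(1, 5, 10))
  n1 <- normalize_amplitude_per_cycle(m)
  expect_equal(unname(n1[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(apply(n1, 2, max)), c(1, 1))
  expect_equal(normalize_amplitude_per_cycle(n1), n1)
  expect_error(normalize_amplitude_per_cycle(cbind(a = c(0, 1), b = c(0, 0))),
               "b")
})

test_that("time normalization is exact on ramps and on identity resampling", {
  ramp <- cbind(x = seq(2, 5, length.out = 17))
  out <- time_normalize(ramp, 101)
  expect_equal(nrow(out), 101L)
  expect_equal(unname(out[, 1]), seq(2, 5, length.out = 101),
               tolerance = 1e-12)
  same <- cbind(x = stats::runif(101))
  expect_equal(time_normalize(same, 101), same, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(time_normalize(ramp[1:3, , drop = FALSE], 101), ">= 4")
})

test_that("subject matrices average cycles then restore column maxima", {
  c1 <- cbind(a = c(0, 1, 0.5), b = c(1, 0, 0.2))
  m_single <- build_subject_matrix(list(c1))
  expect_equal(unclass(m_single), c1, ignore_attr = TRUE)
  m_dup <- build_subject_matrix(list(c1, c1))
  expect_equal(unclass(m_dup), c1, ignore_attr = TRUE)
  # offset peaks: plain averaging would leave column max 0.5
  c2 <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))
  c3 <- cbind(a = c(0, 0, 1), b = c(0, 1, 0))
  m <- build_subject_matrix(list(c2, c3))
  expect_equal(unname(apply(m, 2, max)), c(1, 1))
  expect_error(build_subject_matrix(list(c1, c1[1:2, ])), "shape")
})

test_that("the full chain yields a normalized n_points x n_channels matrix", {
  mod <- default_synergy_model(noise_sigma = 0.1, seed = 8)
  spec <- cohort_spec(n_subjects = 2, n_cycles_per_subject = 3)
  sim <- synthesize_raw_emg(mod, spec, subject_seed = 5)
  m <- suppressWarnings(preprocess(sim$recording, sim$events))
  expect_s3_class(m, "gait_cycle_matrix")
  expect_equal(dim(m), c(101L, 5L))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))
  expect_equal(unname(apply(m, 2, max)), rep(1, 5))
  prov <- attr(m, "provenance")
  expect_equal(prov$n_cycles, 3L)
  expect_equal(prov$envelope_cutoff, 6)
  # alternative grid size honored
  m51 <- suppressWarnings(preprocess(sim$recording, sim$events, n_points = 51))
  expect_equal(nrow(m51), 51L)
  expect_error(preprocess(sim$recording, sim$events[0, ]), "empty")
})
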