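test_that("synergies are ordered by activation peak with energy tie-break", {
  mk <- function(peaks, amps = rep(1, length(peaks))) {
    H <- vapply(seq_along(peaks), function(j) {
      amps[j] * exp(-(seq(0, 100) - peaks[j])^2 / 50)
    }, numeric(101))
    H
  }
  H <- mk(c(60, 10, 90, 30))
  expect_equal(order_synergies(H), c(2L, 4L, 1L, 3L))
  expect_equal(order_synergies(mk(c(10, 30, 60, 90))), 1:4)
  # same peak position: larger energy first
  Ht <- mk(c(50, 50), amps = c(0.5, 2))
  expect_equal(order_synergies(Ht), c(2L, 1L))
})

test_that("permutation alignment recovers known shuffles exactly", {
  mod <- default_synergy_model(noise_sigma = 0)
  H <- make_activation_profiles(mod, 101)
  expect_equal(align_subject_to_reference(H, H), 1:4)
  shuffle <- c(3L, 1L, 4L, 2L)
  expect_equal(align_subject_to_reference(H[, shuffle], H), order(shuffle))
  expect_error(align_subject_to_reference(matrix(1:18, 2), matrix(1:18, 2)),
               "k <= 8")
})

test_that("alignment under small noise agrees with a greedy-matching oracle", {
  mod <- default_synergy_model(noise_sigma = 0)
  H <- make_activation_profiles(mod, 101)
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(4)
    noisy <- pmax(H[, p] + matrix(stats::rnorm(404, 0, 0.05), 101, 4), 0)
    got <- align_subject_to_reference(noisy, H)
    expect_equal(got, order(p))
    expect_equal(got, greedy_match(noisy, H))
  }
})

test_that("group aggregation averages aligned factors", {
  mod <- default_synergy_model(noise_sigma = 0)
  E <- synthesize_envelope(mod)
  dec <- nnmf_decompose(E, 4, seed = 1, n_restarts = 10)
  g1 <- group_mean_synergies(list(dec), group_label = "solo")
  ord <- order_synergies(dec)
  expect_equal(unname(g1$mean_H), unname(dec$H[, ord]))
  g2 <- group_mean_synergies(list(dec, dec), group_label = "dup")
  expect_equal(g2$mean_W, g1$mean_W, ignore_attr = TRUE)
  expect_true(all(g2$sd_W == 0))
  expect_error(group_mean_synergies(list()), "empty")
  dec2 <- nnmf_decompose(E, 3, seed = 1, n_restarts = 5)
  expect_error(group_mean_synergies(list(dec, dec2)), "same k")
})

test_that("group-mean weights recover the generating weights", {
  mod <- default_synergy_model(noise_sigma = 0.1, seed = 31)
  spec <- cohort_spec(n_subjects = 5, weight_jitter_sd = 0.05)
  sets <- fit_envelope_groups(mod, spec, k = 4, seed = 7, n_restarts = 8)
  H_true <- make_activation_profiles(mod, 101)
  perm <- align_subject_to_reference(sets$A$mean_H, H_true)
  cors <- vapply(1:4, function(i) {
    stats::cor(mod$W[i, ], sets$A$mean_W[perm[i], ])
  }, 0)
  expect_true(all(cors >= 0.9))
})

test_that("cross-group correlation is the Pearson matrix with NA guards", {
  mod <- default_synergy_model(noise_sigma = 0)
  H <- make_activation_profiles(mod, 101)
  r_self <- crossgroup_correlation(H, H)
  expect_equal(unname(diag(r_self)), rep(1, 4))
  expect_true(all(r_self >= -1 & r_self <= 1))
  up <- cbind(seq_len(101)); down <- cbind(rev(seq_len(101)))
  expect_equal(crossgroup_correlation(up, down)[1, 1], -1)
  expect_equal(unname(crossgroup_correlation(cbind(c(1, 2, 3)),
                                             cbind(c(2, 4, 6)))[1, 1]), 1)
  expect_warning(rc <- crossgroup_correlation(cbind(rep(1, 5)),
                                              cbind(seq_len(5))), "constant")
  expect_true(is.na(rc[1, 1]))
})

test_that("similarity bands partition [0,1] and match printed readings", {
  expect_identical(classify_similarity(0.431, warn_margin = 0), "moderate")
  expect_identical(classify_similarity(0.0), "small")
  expect_identical(classify_similarity(c(-0.85, 0.29, 0.3, 0.69, 0.7, 1),
                                       warn_margin = 0),
                   c("high", "small", "moderate", "moderate", "high", "high"))
  grid <- seq(0, 1, by = 0.001)
  lab <- classify_similarity(grid, warn_margin = 0)
  expect_false(any(is.na(lab)))
  expect_identical(sort(unique(lab)), c("high", "moderate", "small"))
  # bands are contiguous: label changes exactly at 0.3 and 0.7
  changes <- grid[which(lab[-1] != lab[-length(lab)]) + 1L]
  expect_equal(changes, c(0.3, 0.7))
  expect_error(classify_similarity(1.2), "exceed")
})

test_that("near-boundary correlations trigger the ambiguity warning", {
  expect_warning(classify_similarity(0.302), "inconsistently")
  expect_warning(classify_similarity(0.329), "inconsistently")
  expect_silent(classify_similarity(0.431))
  expect_silent(classify_similarity(0.302, warn_margin = 0))
})

test_that("identical groups produce null weight tests", {
  mod <- default_synergy_model(noise_sigma = 0.15, seed = 17)
  spec <- cohort_spec(n_subjects = 4, weight_jitter_sd = 0.08)
  sets <- fit_envelope_groups(mod, spec, k = 4, seed = 3, n_restarts = 5)
  wt_self <- compare_weights(sets$A, sets$A)
  expect_true(all(abs(wt_self$statistic) < 1e-8, na.rm = TRUE))
  expect_true(all(wt_self$p > 0.999, na.rm = TRUE))
  expect_false(any(wt_self$significant))
  expect_equal(nrow(wt_self), 4L * 5L)
  # Holm adjustment never decreases p
  wt_holm <- compare_weights(sets$A, sets$B, correction = "holm")
  wt_raw <- compare_weights(sets$A, sets$B)
  expect_true(all(wt_holm$p_adj >= wt_raw$p_adj - 1e-12, na.rm = TRUE))
  # nonparametric variant runs and reports the same cells
  wt_np <- compare_weights(sets$A, sets$B, nonparametric = TRUE)
  expect_equal(wt_np$muscle, wt_raw$muscle)
})

test_that("VAF comparison matches the pooled two-sample t formula", {
  a <- c(0.90, 0.901, 0.899, 0.902)
  b <- c(0.95, 0.951, 0.949, 0.952)
  out <- compare_vaf(a, b)
  # hand-computed pooled t
  sp <- sqrt((3 * stats::var(a) + 3 * stats::var(b)) / 6)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_lt(out$p, 1e-6)
  same <- compare_vaf(a, a)
  expect_gt(same$p, 0.999)
  expect_error(compare_vaf(list(`2` = a), list(`3` = b)), "no common k")
})

test_that("the comparison report assembles all pieces coherently", {
  mod <- default_synergy_model(noise_sigma = 0.15, seed = 23)
  spec <- cohort_spec(n_subjects = 4, weight_jitter_sd = 0.08)
  sets <- fit_envelope_groups(mod, spec, k = 4, seed = 5, n_restarts = 5)
  rep <- suppressWarnings(compare_groups(
    sets$A, sets$B, alpha = 0.05,
    vafsA = list(`4` = c(0.95, 0.96, 0.94, 0.95)),
    vafsB = list(`4` = c(0.95, 0.95, 0.96, 0.94))))
  expect_s3_class(rep, "synergy_comparison")
  expect_equal(dim(rep$correlation_matrix), c(4L, 4L))
  expect_true(all(rep$correlation_matrix >= -1 & rep$correlation_matrix <= 1))
  expect_identical(dim(rep$similarity_class), dim(rep$correlation_matrix))
  # same ground truth: matched synergies should correlate highly
  expect_true(all(rep$matched_pairs$r > 0.7))
  expect_identical(rep$matched_pairs$similarity, rep("high", 4))
  expect_equal(nrow(rep$weight_tests), 20L)
  expect_equal(rep$vaf_tests$k, 4L)
  expect_output(print(rep), "Cross-group correlation")
})
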