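test_that("per-muscle VAF matches hand arithmetic in both forms", {
  expect_equal(unname(vaf_per_muscle(cbind(c(1, 1)), cbind(c(1, 1)))), 1)
  expect_equal(unname(vaf_per_muscle(cbind(c(1, 1)), cbind(c(0, 0)))), 0)
  expect_equal(unname(vaf_per_muscle(cbind(c(2, 0)), cbind(c(1, 1)))), 0.5)
  # the unsquared (as-printed) variant is sign-sensitive and unbounded:
  # 1 - ((0-1)+(0-1))/(1+1) = 2
  expect_equal(unname(vaf_per_muscle(cbind(c(1, 1)), cbind(c(0, 0)),
                                     form = "unsquared")), 2)
  expect_error(vaf_per_muscle(cbind(c(0, 0)), cbind(c(1, 1))), "all zero")
})

test_that("global VAF pools energy over the matrix", {
  M <- cbind(a = c(1, 2), b = c(3, 1))
  expect_equal(vaf_global(M, M), 1)
  expect_equal(vaf_global(M, M * 0), 0)
  # with equal-energy columns the pooled VAF is the per-muscle mean, hence
  # between the per-muscle extremes
  Me <- cbind(c(1, 2), c(2, 1))
  rec <- cbind(c(1, 1.5), c(1, 1))
  vpm <- vaf_per_muscle(Me, rec)
  vg <- vaf_global(Me, rec)
  expect_gte(vg, min(vpm))
  expect_lte(vg, max(vpm))
  expect_error(vaf_global(Me * 0, rec), "all zero")
})

test_that("rank-1 matrices are factorized essentially exactly", {
  set.seed(42)
  h <- stats::runif(30); w <- stats::runif(4)
  M <- outer(h, w)
  dec <- nnmf_decompose(M, 1, seed = 1, n_restarts = 5)
  expect_gte(dec$vaf_global, 0.999)
  expect_gte(stats::cor(w, dec$W[1, ]), 0.999)
})

test_that("decomposition is deterministic given matrix, k and seed", {
  mod <- tiny_model(noise_sigma = 0.3, seed = 6)
  M <- synthesize_envelope(mod)
  d1 <- nnmf_decompose(M, 2, seed = 4, n_restarts = 5)
  d2 <- nnmf_decompose(M, 2, seed = 4, n_restarts = 5)
  expect_identical(d1$H, d2$H)
  expect_identical(d1$W, d2$W)
})

test_that("factors are nonnegative and canonicalized, reconstruction intact", {
  mod <- tiny_model(noise_sigma = 0.2, seed = 2)
  M <- synthesize_envelope(mod)
  dec <- nnmf_decompose(M, 2, seed = 1, n_restarts = 5)
  expect_gte(min(dec$H), 0)
  expect_gte(min(dec$W), 0)
  expect_equal(unname(apply(dec$W, 1, max)), c(1, 1))
  expect_equal(reconstruct(dec), dec$H %*% dec$W)
  # VAF is invariant under the scale/permutation ambiguity of the factors
  perm <- c(2, 1); s <- c(0.3, 4)
  H2 <- sweep(dec$H[, perm], 2, s, "*")
  W2 <- sweep(dec$W[perm, ], 1, s, "/")
  expect_equal(vaf_per_muscle(M, H2 %*% W2), dec$vaf_per_muscle)
  # S3 surface of the fit object
  expect_equal(coef(dec), dec$W)
  expect_equal(fitted(dec), reconstruct(dec))
  expect_equal(residuals(dec), unclass(M) - reconstruct(dec),
               ignore_attr = TRUE)
})

test_that("invalid factorization inputs are rejected", {
  M <- matrix(1:6, 3, 2)
  expect_error(nnmf_decompose(M - 10, 1), "nonnegative")
  expect_error(nnmf_decompose(M, 0), "k must be")
  expect_warning(nnmf_decompose(M, 3, n_restarts = 2, max_iter = 50),
                 "exceeds")
})

test_that("multiplicative updates never increase the loss", {
  mod <- tiny_model(noise_sigma = 0.4, seed = 3)
  M <- synthesize_envelope(mod)
  losses <- vapply(c(1, 5, 20, 100, 400), function(n_it) {
    nnmf_decompose(M, 2, seed = 9, n_restarts = 1, max_iter = n_it,
                   tol = 0)$frobenius_loss
  }, 0)
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("k = n_muscles reconstructs a generic small matrix almost exactly", {
  set.seed(11)
  M <- matrix(stats::runif(12 * 3), 12, 3)
  dec <- nnmf_decompose(M, 3, seed = 2, n_restarts = 10)
  expect_gte(dec$vaf_global, 0.999)
})

test_that("noiseless four-synergy structure is recovered at k = 4", {
  mod <- default_synergy_model(noise_sigma = 0)
  E <- synthesize_envelope(mod)
  H_true <- make_activation_profiles(mod, 101)
  dec <- nnmf_decompose(E, 4, seed = 1, n_restarts = 20)
  cors <- matched_weight_cors(dec, mod$W, H_true)
  expect_true(all(cors >= 0.95))
  expect_gte(dec$vaf_global, 0.999)
})

test_that("achieved loss matches an independent ANLS oracle within 1%", {
  skip_if_not_installed("pracma")
  set.seed(123)
  rel_gap <- vapply(1:20, function(i) {
    n <- sample(6:12, 1); m <- sample(3:5, 1); k <- sample(2:3, 1)
    M <- matrix(stats::runif(n * m, 0.05, 1), n, m)
    ours <- nnmf_decompose(M, k, seed = i, n_restarts = 10,
                           max_iter = 2000, tol = 1e-9)$frobenius_loss
    oracle <- nmf_anls_oracle(M, k, n_restarts = 5, seed = 1000 + i)
    (ours - oracle) / max(oracle, 1e-12)
  }, 0)
  expect_true(all(abs(rel_gap) <= 0.01))
})

test_that("selection stops at the smallest k meeting the per-muscle rule", {
  mod <- default_synergy_model(noise_sigma = 0)
  E <- synthesize_envelope(mod)
  curve <- select_num_synergies(E, seed = 2, n_restarts = 10)
  expect_equal(curve$k_selected, 4L)
  expect_true(curve$criterion_met)
  expect_true(all(selected_decomposition(curve)$vaf_per_muscle > 0.9))
  # every k below the selected one fails the rule
  below <- curve$vaf_table$min_vaf_muscle[curve$vaf_table$k < 4]
  expect_true(all(below <= 0.9))

  # rank-1 input needs a single synergy
  h <- make_activation_profiles(tiny_model(), 101)[, 1]
  M1 <- outer(h, c(1, 0.5, 0.2)) + 1e-6
  c1 <- select_num_synergies(M1, seed = 1, n_restarts = 5)
  expect_equal(c1$k_selected, 1L)
})

test_that("an unreachable threshold flags the curve and returns k_max", {
  mod <- tiny_model(noise_sigma = 0.6, seed = 12)
  M <- synthesize_envelope(mod)
  expect_warning(
    curve <- select_num_synergies(M, threshold = 0.999999, k_max = 3,
                                  seed = 1, n_restarts = 4, max_iter = 300),
    "never reached"
  )
  expect_false(curve$criterion_met)
  expect_equal(curve$k_selected, 3L)
})

test_that("warm-started selection gives a monotone global VAF curve", {
  for (seed in 1:5) {
    mod <- default_synergy_model(noise_sigma = 0.4, seed = seed)
    M <- synthesize_envelope(mod)
    M <- sweep(M, 2, apply(M, 2, max), "/")
    curve <- suppressWarnings(
      select_num_synergies(M, threshold = 0.999, k_max = 5, seed = seed,
                           n_restarts = 4, max_iter = 500, tol = 1e-6)
    )
    expect_true(all(diff(curve$vaf_table$vaf_global) >= -1e-9))
  }
})
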