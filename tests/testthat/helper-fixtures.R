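# Shared fixtures: small ground-truth models and cohort helpers. Everything
# is generated in code; no stored data.

five_muscles <- c("GA", "TA", "VL", "GM", "BF")

# Two well-separated synergies over three muscles: quick fixture for unit
# tests that only need some low-rank nonnegative structure.
tiny_model <- function(noise_sigma = 0, seed = 1L) {
  synergy_model(
    W = rbind(c(1, 0.2, 0.05), c(0.1, 0.3, 1)),
    burst_centers = c(25, 75), burst_widths = c(10, 10),
    noise_sigma = noise_sigma, seed = seed,
    muscles = c("m1", "m2", "m3")
  )
}

# Envelope-level two-group cohort fitted at a fixed k, mirroring the
# pipeline's submaximal normalization (columns scaled to max 1) without the
# raw-EMG synthesis. Returns synergy_group objects ready for compare_*().
fit_envelope_groups <- function(model, spec, k, seed = 1L, n_restarts = 5L,
                                max_iter = 400L, tol = 1e-5) {
  cohort <- generate_cohort(model, spec, level = "envelope")
  sets <- lapply(names(cohort$groups), function(g) {
    decs <- lapply(cohort$groups[[g]], function(sub) {
      E <- sub$envelope
      M <- sweep(E, 2L, apply(E, 2L, max), "/")
      nnmf_decompose(M, k, seed = derive_seed2(seed, sub$seed),
                     n_restarts = n_restarts, max_iter = max_iter, tol = tol)
    })
    group_mean_synergies(unname(decs), group_label = g)
  })
  names(sets) <- names(cohort$groups)
  sets
}

# small deterministic seed combiner for test fixtures
derive_seed2 <- function(a, b) as.integer((as.double(a) * 1009 + as.double(b)) %% 2147483629)

# Correlation between each true weight row and its matched recovered row,
# using activation-profile matching to resolve the permutation ambiguity.
matched_weight_cors <- function(dec, W_true, H_true) {
  perm <- align_subject_to_reference(dec$H, H_true)
  vapply(seq_len(nrow(W_true)), function(i) {
    stats::cor(W_true[i, ], dec$W[perm[i], ])
  }, 0)
}
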