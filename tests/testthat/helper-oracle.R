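# Independent NMF oracle: alternating nonnegative least squares solved
# column-/row-wise with pracma::lsqnonneg. Entirely different algorithm from
# the package's multiplicative updates; used only to cross-check achieved
# Frobenius loss on small problems.
nmf_anls_oracle <- function(M, k, n_restarts = 5L, n_iter = 80L, seed = 1L) {
  n <- nrow(M); m <- ncol(M)
  best <- Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    H <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    W <- matrix(stats::runif(k * m, 0.1, 1), k, m)
    for (it in seq_len(n_iter)) {
      W <- vapply(seq_len(m), function(j) pracma::lsqnonneg(H, M[, j])$x,
                  numeric(k))
      W <- matrix(W, k, m)
      if (all(rowSums(W) == 0)) break
      Ht <- vapply(seq_len(n), function(i) pracma::lsqnonneg(t(W), M[i, ])$x,
                   numeric(k))
      H <- t(matrix(Ht, k, n))
    }
    best <- min(best, sqrt(sum((M - H %*% W)^2)))
  }
  best
}

# Greedy correlation matching: repeatedly pair the highest-correlation
# (reference, subject) columns. Used as an independent check on the
# exhaustive permutation search where greedy is provably adequate (clear
# margins).
greedy_match <- function(subject_H, reference_H) {
  k <- ncol(subject_H)
  cors <- stats::cor(reference_H, subject_H)
  perm <- integer(k)
  for (step in seq_len(k)) {
    ij <- which(cors == max(cors, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    perm[ij[1L]] <- ij[2L]
    cors[ij[1L], ] <- -Inf
    cors[, ij[2L]] <- -Inf
  }
  perm
}
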