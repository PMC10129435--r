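# Nonnegative matrix factorization of envelope matrices by Lee-Seung
# multiplicative updates (Frobenius objective), with seeded restarts,
# canonicalization and VAF computation.

# One multiplicative-update run from a given nonnegative initialization.
# Loss is the Frobenius norm ||M - HW||_F; each update is non-increasing.
ls_update_run <- function(M, H, W, max_iter, tol, eps = 1e-12) {
  loss <- sqrt(sum((M - H %*% W)^2))
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (M %*% t(W)) / (H %*% (W %*% t(W)) + eps)
    W <- W * (t(H) %*% M) / ((t(H) %*% H) %*% W + eps)
    new_loss <- sqrt(sum((M - H %*% W)^2))
    if (loss > 0 && (loss - new_loss) / loss < tol) {
      loss <- new_loss
      break
    }
    loss <- new_loss
  }
  list(H = H, W = W, loss = loss, iters = it)
}

random_init <- function(M, k) {
  n <- nrow(M); m <- ncol(M)
  # uniform (0,1] factors scaled so mean(HW) matches mean(M)
  s <- sqrt(max(mean(M), .Machine$double.eps) / (k * 0.25))
  list(H = matrix(stats::runif(n * k), n, k) * s,
       W = matrix(stats::runif(k * m), k, m) * s)
}

canonicalize_factors <- function(H, W) {
  s <- apply(W, 1L, max)
  s[s == 0] <- 1
  list(H = H * rep(s, each = nrow(H)), W = W / s)
}

#' Factorize an envelope matrix into muscle synergies
#'
#' Fits the synergy model `M = H W` by nonnegative matrix factorization:
#' `H` (`n_points` x `k`) holds the synergy activation coefficients and `W`
#' (`k` x `n_muscles`) the muscle synergy weights. Minimizes the Frobenius
#' reconstruction error with Lee-Seung multiplicative updates from
#' `n_restarts` seeded random nonnegative initializations; the lowest-loss
#' restart wins (ties go to the earliest seed). The result is canonicalized
#' so each row of `W` has maximum 1, the compensating scale absorbed into the
#' columns of `H` — weights are then "relative muscle weights" on a fixed
#' scale, comparable across subjects.
#'
#' @param M nonnegative matrix (or [gait_cycle_matrix()]), points x muscles.
#' @param k number of synergies (>= 1). Values above the muscle count are
#'   allowed but warned about.
#' @param seed integer; restart `r` uses seed `seed + r - 1`.
#' @param n_restarts number of random initializations (default 20).
#' @param max_iter maximum multiplicative updates per restart (default 2000).
#' @param tol stop a restart when the relative loss decrease falls below this
#'   (default 1e-6).
#' @param warm_start optional list with elements `H`, `W`: an extra candidate
#'   initialization run alongside the random restarts (used by
#'   [select_num_synergies()] to make the VAF curve monotone in `k`).
#' @return An object of class `synergy_nmf` with components `H`, `W`, `k`,
#'   `frobenius_loss`, `vaf_per_muscle`, `vaf_global`, `seed_used`,
#'   `n_iterations`, `M` (the input), and `channel_labels`.
#' @seealso [vaf_per_muscle()], [select_num_synergies()]
#' @export
nnmf_decompose <- function(M, k, seed = 1L, n_restarts = 20L, max_iter = 2000L,
                           tol = 1e-6, warm_start = NULL) {
  lbl <- attr(M, "channel_labels") %||% colnames(M)
  M <- unclass(as.matrix(M))
  if (any(!is.finite(M)) || any(M < 0)) {
    stopf("M must be finite and nonnegative")
  }
  if (!is_count(k, 1L)) stopf("k must be an integer >= 1")
  k <- as.integer(k)
  if (k > ncol(M)) {
    warnf("k = %d exceeds the number of muscles (%d); factors will be rank-deficient",
          k, ncol(M))
  }
  if (!is_count(n_restarts, 1L)) stopf("n_restarts must be >= 1")

  candidates <- vector("list", n_restarts + !is.null(warm_start))
  for (r in seq_len(n_restarts)) {
    init <- with_seed(seed + r - 1L, random_init(M, k))
    fit <- ls_update_run(M, init$H, init$W, max_iter, tol)
    fit$seed_used <- seed + r - 1L
    candidates[[r]] <- fit
  }
  if (!is.null(warm_start)) {
    stopifnot(is.matrix(warm_start$H), is.matrix(warm_start$W))
    fit <- ls_update_run(M, pmax(warm_start$H, 0), pmax(warm_start$W, 0),
                         max_iter, tol)
    fit$seed_used <- NA_integer_
    candidates[[n_restarts + 1L]] <- fit
  }
  losses <- vapply(candidates, `[[`, 0, "loss")
  best <- candidates[[which.min(losses)]]  # first minimum = lowest seed on ties

  cf <- canonicalize_factors(best$H, best$W)
  rec <- cf$H %*% cf$W
  colnames(cf$W) <- lbl
  colnames(cf$H) <- rownames(cf$W) <- paste0("S", seq_len(k))
  structure(
    list(H = cf$H, W = cf$W, k = k,
         frobenius_loss = best$loss,
         vaf_per_muscle = vaf_per_muscle(M, rec),
         vaf_global = vaf_global(M, rec),
         seed_used = best$seed_used, n_iterations = best$iters,
         M = M, channel_labels = lbl),
    class = "synergy_nmf"
  )
}

#' Reconstruct the envelope matrix from a decomposition
#'
#' @param dec a `synergy_nmf` object.
#' @return The matrix product `H %*% W`.
#' @export
reconstruct <- function(dec) {
  stopifnot(inherits(dec, "synergy_nmf"))
  dec$H %*% dec$W
}

#' Variance accounted for, per muscle
#'
#' For each muscle column, `VAF = 1 - sum((rec - exp)^2) / sum(exp^2)` — the
#' uncentered squared-residual form standard in synergy analysis
#' (`form = "squared"`, the default). `form = "unsquared"` computes
#' `1 - sum(rec - exp) / sum(exp)`, a sign-sensitive variant occasionally
#' printed in the literature; it can exceed 1 and is provided for comparison
#' only.
#'
#' @param M observed matrix (at least one positive entry per column).
#' @param M_rec reconstructed matrix of the same shape.
#' @param form `"squared"` (default) or `"unsquared"`.
#' @return Numeric vector of length `n_muscles`, each entry at most 1 for the
#'   squared form.
#' @export
vaf_per_muscle <- function(M, M_rec, form = c("squared", "unsquared")) {
  form <- match.arg(form)
  M <- unclass(as.matrix(M)); M_rec <- as.matrix(M_rec)
  if (!identical(dim(M), dim(M_rec))) stopf("M and M_rec shapes differ")
  denom <- if (form == "squared") colSums(M^2) else colSums(M)
  if (any(denom == 0)) {
    stopf("column(s) %s of M are all zero; VAF undefined",
          paste(which(denom == 0), collapse = ", "))
  }
  num <- if (form == "squared") colSums((M_rec - M)^2) else colSums(M_rec - M)
  v <- 1 - num / denom
  names(v) <- colnames(M)
  v
}

#' Variance accounted for, pooled over all muscles and time points
#'
#' @inheritParams vaf_per_muscle
#' @return A single number, at most 1 for the squared form.
#' @export
vaf_global <- function(M, M_rec, form = c("squared", "unsquared")) {
  form <- match.arg(form)
  M <- unclass(as.matrix(M)); M_rec <- as.matrix(M_rec)
  if (!identical(dim(M), dim(M_rec))) stopf("M and M_rec shapes differ")
  denom <- if (form == "squared") sum(M^2) else sum(M)
  if (denom == 0) stopf("M is all zero; VAF undefined")
  num <- if (form == "squared") sum((M_rec - M)^2) else sum(M_rec - M)
  1 - num / denom
}

#' @export
print.synergy_nmf <- function(x, ...) {
  cat(sprintf("Muscle synergy decomposition: k = %d, %d points x %d muscles\n",
              x$k, nrow(x$H), ncol(x$W)))
  cat(sprintf("  Frobenius loss %.4g after %d iterations (restart seed %s)\n",
              x$frobenius_loss, x$n_iterations, format(x$seed_used)))
  cat(sprintf("  global VAF %.4f; per-muscle VAF: %s\n", x$vaf_global,
              paste(sprintf("%s=%.3f", names(x$vaf_per_muscle),
                            x$vaf_per_muscle), collapse = ", ")))
  invisible(x)
}

#' @export
summary.synergy_nmf <- function(object, ...) {
  peaks <- round(100 * (apply(object$H, 2L, which.max) - 1) / (nrow(object$H) - 1))
  out <- list(k = object$k, W = object$W, peak_pct = peaks,
              vaf_per_muscle = object$vaf_per_muscle,
              vaf_global = object$vaf_global,
              frobenius_loss = object$frobenius_loss)
  class(out) <- "summary.synergy_nmf"
  out
}

#' @export
print.summary.synergy_nmf <- function(x, ...) {
  cat(sprintf("Synergy decomposition with k = %d\n", x$k))
  cat("Activation peaks (%% of cycle):", paste(x$peak_pct, collapse = ", "), "\n")
  cat("Relative muscle weights W (rows max-1):\n")
  print(round(x$W, 3))
  cat(sprintf("Global VAF: %.4f  (loss %.4g)\n", x$vaf_global, x$frobenius_loss))
  cat("Per-muscle VAF:\n")
  print(round(x$vaf_per_muscle, 4))
  invisible(x)
}

#' @export
coef.synergy_nmf <- function(object, ...) object$W

#' @export
fitted.synergy_nmf <- function(object, ...) reconstruct(object)

#' @export
residuals.synergy_nmf <- function(object, ...) object$M - reconstruct(object)

#' @export
predict.synergy_nmf <- function(object, ...) reconstruct(object)

#' Plot a synergy decomposition
#'
#' Draws the activation coefficients (one curve per synergy over the gait
#' cycle) and the relative muscle weights (one bar group per synergy).
#'
#' @param x a `synergy_nmf`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.synergy_nmf <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pct <- seq(0, 100, length.out = nrow(x$H))
  graphics::matplot(pct, x$H, type = "l", lty = 1, xlab = "% gait cycle",
                    ylab = "activation coefficient",
                    main = sprintf("H (k = %d)", x$k), ...)
  graphics::barplot(x$W, beside = TRUE, legend.text = rownames(x$W),
                    xlab = "muscle", ylab = "relative weight", main = "W")
  invisible(x)
}
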