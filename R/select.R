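#' Select the number of synergies by the per-muscle VAF rule
#'
#' Fits decompositions at `k = 1, 2, ...` in order and stops at the first `k`
#' for which the VAF of every muscle exceeds `threshold` (default 0.9) —
#' additional synergies are then deemed unnecessary. If no `k` up to `k_max`
#' meets the criterion the curve is returned with `criterion_met = FALSE`,
#' `k_selected = k_max`, and a warning.
#'
#' Each fit at `k + 1` includes, alongside fresh random restarts, one
#' warm-start initialization built from the best `k`-solution padded with a
#' small random extra component. Multiplicative updates never increase the
#' loss, so the best loss — and hence global VAF — is non-decreasing in `k`,
#' which keeps the stopping rule well defined (independent random restarts
#' alone can dip non-monotonically).
#'
#' @param M nonnegative points x muscles matrix (or [gait_cycle_matrix()]).
#' @param threshold per-muscle VAF threshold in (0, 1) (default 0.9).
#' @param k_max largest synergy count tried (default: number of muscles).
#' @param seed,n_restarts,max_iter,tol passed to [nnmf_decompose()].
#' @return An object of class `synergy_curve`: list with `per_k` (one
#'   `synergy_nmf` per k), `vaf_table` (data frame of per-k VAF values),
#'   `k_selected`, `criterion_met`, `threshold`.
#' @export
select_num_synergies <- function(M, threshold = 0.9, k_max = NULL, seed = 1L,
                                 n_restarts = 20L, max_iter = 2000L,
                                 tol = 1e-6) {
  if (!is_number(threshold) || threshold <= 0 || threshold >= 1) {
    stopf("threshold must lie in (0, 1)")
  }
  n_mus <- ncol(M)
  k_max <- k_max %||% n_mus
  if (!is_count(k_max, 1L)) stopf("k_max must be an integer >= 1")

  per_k <- list()
  k_selected <- NA_integer_
  prev <- NULL
  Mm <- unclass(as.matrix(M))
  for (k in seq_len(k_max)) {
    ws <- NULL
    if (!is.null(prev)) {
      # pad the best k-solution with a tiny random extra component; its
      # initial loss is essentially the previous optimum, so updates can
      # only improve on it
      small <- 1e-3 * mean(Mm)
      ws <- with_seed(derive_seed(seed, 10000L + k), list(
        H = cbind(prev$H, matrix(stats::runif(nrow(prev$H)) * small,
                                 ncol = 1L)),
        W = rbind(prev$W, matrix(stats::runif(ncol(prev$W)) * small,
                                 nrow = 1L))
      ))
    }
    dec <- nnmf_decompose(M, k, seed = seed, n_restarts = n_restarts,
                          max_iter = max_iter, tol = tol, warm_start = ws)
    if (!is.null(prev) && dec$frobenius_loss > prev$frobenius_loss + 1e-10) {
      # rare: warm start stopped early above the previous optimum; rerun it
      # with a tighter tolerance
      dec2 <- nnmf_decompose(M, k, seed = seed, n_restarts = 1L,
                             max_iter = 4L * max_iter, tol = tol * 1e-3,
                             warm_start = ws)
      if (dec2$frobenius_loss < dec$frobenius_loss) dec <- dec2
    }
    per_k[[k]] <- dec
    prev <- dec
    if (is.na(k_selected) && min(dec$vaf_per_muscle) > threshold) {
      k_selected <- k
      break
    }
  }
  criterion_met <- !is.na(k_selected)
  if (!criterion_met) {
    k_selected <- k_max
    warnf("per-muscle VAF > %g never reached up to k_max = %d (best min VAF %.3f); returning k_max",
          threshold, k_max, min(per_k[[k_max]]$vaf_per_muscle))
  }
  ks <- seq_along(per_k)
  vaf_table <- data.frame(
    k = ks,
    vaf_global = vapply(per_k, `[[`, 0, "vaf_global"),
    min_vaf_muscle = vapply(per_k, function(d) min(d$vaf_per_muscle), 0)
  )
  vpm <- t(vapply(per_k, `[[`, numeric(n_mus), "vaf_per_muscle"))
  colnames(vpm) <- paste0("vaf_", colnames(M) %||% paste0("ch", seq_len(n_mus)))
  vaf_table <- cbind(vaf_table, as.data.frame(vpm))
  structure(
    list(per_k = per_k, vaf_table = vaf_table, k_selected = k_selected,
         criterion_met = criterion_met, threshold = threshold),
    class = "synergy_curve"
  )
}

#' Decomposition at the selected synergy count
#'
#' @param curve a `synergy_curve`.
#' @return The `synergy_nmf` fitted at `curve$k_selected`.
#' @export
selected_decomposition <- function(curve) {
  stopifnot(inherits(curve, "synergy_curve"))
  curve$per_k[[curve$k_selected]]
}

#' @export
print.synergy_curve <- function(x, ...) {
  cat(sprintf("Synergy selection curve (threshold %g): k_selected = %d%s\n",
              x$threshold, x$k_selected,
              if (x$criterion_met) "" else " [criterion never met]"))
  print(round(x$vaf_table, 4), row.names = FALSE)
  invisible(x)
}

#' Plot the VAF selection curve
#'
#' @param x a `synergy_curve`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.synergy_curve <- function(x, ...) {
  vt <- x$vaf_table
  graphics::matplot(vt$k, cbind(vt$vaf_global, vt$min_vaf_muscle), type = "b",
                    pch = c(19, 1), lty = 1:2, col = c("black", "grey40"),
                    xlab = "number of synergies k", ylab = "VAF",
                    ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 3)
  graphics::abline(v = x$k_selected, lty = 3, col = "grey60")
  graphics::legend("bottomright", c("global VAF", "min per-muscle VAF"),
                   pch = c(19, 1), lty = 1:2, col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}
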