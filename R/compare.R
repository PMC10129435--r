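# Cross-subject and cross-group comparison of synergies: ordering, optimal
# permutation matching, group means, Pearson similarity with banded labels,
# and independent-samples tests on relative muscle weights and VAF.

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Canonical ordering of synergies within one decomposition
#'
#' NMF output order is arbitrary; synergies are put in gait-phase order by
#' sorting on the cycle-percent position of each activation column's maximum,
#' ascending, ties broken by larger total activation energy first. This makes
#' "first synergy ... fourth synergy" well defined.
#'
#' @param dec a `synergy_nmf`, or an activation matrix `H`.
#' @return Integer permutation `p` such that `H[, p]` is in canonical order.
#' @export
order_synergies <- function(dec) {
  H <- if (inherits(dec, "synergy_nmf")) dec$H else as.matrix(dec)
  peaks <- apply(H, 2L, which.max)
  energy <- colSums(H^2)
  order(peaks, -energy)
}

#' Match a subject's synergies to a reference by optimal permutation
#'
#' Finds the column permutation of `subject_H` maximizing the sum of Pearson
#' correlations with the matched columns of `reference_H`, by exhaustive
#' search over all `k!` permutations (exact for the small `k` of synergy
#' analysis; refuses `k > 8`).
#'
#' @param subject_H,reference_H activation matrices with equal dimensions.
#' @return Integer vector `p`: `subject_H[, p]` is aligned to `reference_H`.
#' @export
align_subject_to_reference <- function(subject_H, reference_H) {
  subject_H <- as.matrix(subject_H); reference_H <- as.matrix(reference_H)
  if (!identical(dim(subject_H), dim(reference_H))) {
    stopf("subject and reference activation matrices must share dimensions")
  }
  k <- ncol(subject_H)
  if (k > 8L) {
    stopf("exhaustive matching supports k <= 8; extend with an assignment algorithm for larger k")
  }
  cors <- suppressWarnings(stats::cor(reference_H, subject_H))
  cors[!is.finite(cors)] <- 0  # constant columns carry no matching signal
  best <- NULL; best_score <- -Inf
  for (p in all_permutations(k)) {
    score <- sum(cors[cbind(seq_len(k), p)])
    if (score > best_score) {
      best_score <- score
      best <- p
    }
  }
  as.integer(best)
}

#' Aggregate aligned decompositions into a group synergy set
#'
#' Aligns every subject to a reference subject (by default the first, after
#' putting the reference itself in canonical gait-phase order) and averages:
#' `mean_H` is the element-wise mean of aligned activation coefficients,
#' `mean_W`/`sd_W` the mean and SD of aligned weight rows.
#'
#' @param decs list of `synergy_nmf` objects, all with the same `k`.
#' @param group_label name for the group.
#' @param reference index of the reference subject (default 1).
#' @return An object of class `synergy_group` with fields `group_label`,
#'   `decompositions`, `orderings` (per-subject permutations), `mean_H`,
#'   `mean_W`, `sd_W`, `k`, `muscles`.
#' @export
group_mean_synergies <- function(decs, group_label = "group", reference = 1L) {
  if (length(decs) < 1L) stopf("empty group")
  ks <- vapply(decs, `[[`, 0L, "k")
  if (length(unique(ks)) != 1L) {
    stopf("all subjects must share the same k (got %s)",
          paste(unique(ks), collapse = ", "))
  }
  k <- ks[[1L]]
  ref_ord <- order_synergies(decs[[reference]])
  ref_H <- decs[[reference]]$H[, ref_ord, drop = FALSE]
  orderings <- lapply(decs, function(d) {
    align_subject_to_reference(d$H, ref_H)
  })
  H_arr <- lapply(seq_along(decs), function(i) {
    decs[[i]]$H[, orderings[[i]], drop = FALSE]
  })
  W_arr <- lapply(seq_along(decs), function(i) {
    decs[[i]]$W[orderings[[i]], , drop = FALSE]
  })
  mean_H <- Reduce(`+`, H_arr) / length(H_arr)
  mean_W <- Reduce(`+`, W_arr) / length(W_arr)
  sd_W <- if (length(W_arr) > 1L) {
    sqrt(Reduce(`+`, lapply(W_arr, function(w) (w - mean_W)^2)) /
           (length(W_arr) - 1L))
  } else mean_W * 0
  muscles <- decs[[1L]]$channel_labels %||% colnames(decs[[1L]]$W)
  rownames(mean_W) <- rownames(sd_W) <- colnames(mean_H) <-
    paste0("S", seq_len(k))
  structure(
    list(group_label = group_label, decompositions = decs,
         orderings = orderings, aligned_W = W_arr, mean_H = mean_H,
         mean_W = mean_W, sd_W = sd_W, k = k, muscles = muscles),
    class = "synergy_group"
  )
}

#' @export
print.synergy_group <- function(x, ...) {
  cat(sprintf("Synergy group '%s': %d subjects, k = %d\n", x$group_label,
              length(x$decompositions), x$k))
  cat("mean W (+/- SD):\n")
  print(round(x$mean_W, 3))
  invisible(x)
}

#' Cross-group correlation of mean activation coefficients
#'
#' Entry (i, j) is the Pearson correlation over the cycle grid between group
#' A's i-th and group B's j-th mean activation coefficient. Constant columns
#' give undefined correlations, reported as `NA` with a warning.
#'
#' @param meanH_A,meanH_B `n_points` x `k` matrices with equal dimensions.
#' @return `k` x `k` numeric matrix.
#' @export
crossgroup_correlation <- function(meanH_A, meanH_B) {
  meanH_A <- as.matrix(meanH_A); meanH_B <- as.matrix(meanH_B)
  if (!identical(dim(meanH_A), dim(meanH_B))) {
    stopf("mean activation matrices must share dimensions")
  }
  const_A <- apply(meanH_A, 2L, stats::sd) == 0
  const_B <- apply(meanH_B, 2L, stats::sd) == 0
  if (any(const_A) || any(const_B)) {
    warnf("constant activation column(s); correlations reported as NA")
  }
  r <- suppressWarnings(stats::cor(meanH_A, meanH_B))
  dimnames(r) <- list(paste0("A_S", seq_len(ncol(meanH_A))),
                      paste0("B_S", seq_len(ncol(meanH_B))))
  r
}

#' Similarity class of a Pearson correlation
#'
#' Maps `|r|` onto the conventional bands: `[0, 0.3)` small, `[0.3, 0.7)`
#' moderate, `[0.7, 1]` high (left-closed intervals, so the nominal gaps at
#' 0.29-0.3 and 0.69-0.7 are covered). Values within `warn_margin` of a band
#' edge trigger a warning, because the literature labels near-boundary values
#' inconsistently (correlations just above 0.3 are sometimes read as "weak").
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @param warn_margin half-width of the boundary warning zone (default 0.05;
#'   set 0 to disable).
#' @return Character vector with values `"small"`, `"moderate"`, `"high"`
#'   (`NA` maps to `NA`).
#' @export
classify_similarity <- function(r, warn_margin = 0.05) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stopf("|r| must not exceed 1")
  a <- abs(r)
  lab <- ifelse(is.na(a), NA_character_,
                ifelse(a < 0.3, "small", ifelse(a < 0.7, "moderate", "high")))
  if (warn_margin > 0) {
    near <- !is.na(a) & (abs(a - 0.3) < warn_margin | abs(a - 0.7) < warn_margin)
    if (any(near)) {
      warnf("correlation(s) %s fall within %g of a similarity-band edge; band labels near 0.3 and 0.7 are reported inconsistently in the literature",
            paste(format(r[near], digits = 3), collapse = ", "), warn_margin)
    }
  }
  lab
}

shapiro_p <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

#' Compare relative muscle weights between two groups
#'
#' For every (synergy, muscle) cell, runs an independent-samples t-test on the
#' per-subject aligned relative weights, reporting the statistic, two-sided
#' p-value, group means and SDs, a significance flag at `alpha`, and
#' Shapiro-Wilk normality p-values per group sample. Cells with zero variance
#' in both groups are undefined and reported with `NA` statistics.
#'
#' @param groupA,groupB `synergy_group` objects with equal `k` and muscles.
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (default, uncorrected across the k x m cells) or
#'   `"holm"`.
#' @param nonparametric if `TRUE`, use Mann-Whitney (Wilcoxon rank-sum) tests
#'   instead of t-tests.
#' @param var_equal passed to [stats::t.test()] (default `TRUE`: classical
#'   pooled-variance independent-samples t-test).
#' @return Data frame, one row per (synergy, muscle).
#' @export
compare_weights <- function(groupA, groupB, alpha = 0.05,
                            correction = c("none", "holm"),
                            nonparametric = FALSE, var_equal = TRUE) {
  stopifnot(inherits(groupA, "synergy_group"), inherits(groupB, "synergy_group"))
  correction <- match.arg(correction)
  if (groupA$k != groupB$k) stopf("groups have different k")
  if (!identical(groupA$muscles, groupB$muscles)) {
    stopf("groups have different muscle sets")
  }
  if (length(groupA$decompositions) < 2L || length(groupB$decompositions) < 2L) {
    stopf("need >= 2 subjects per group")
  }
  k <- groupA$k; muscles <- groupA$muscles
  rows <- list()
  for (s in seq_len(k)) {
    for (m in seq_along(muscles)) {
      xa <- vapply(groupA$aligned_W, function(w) w[s, m], 0)
      xb <- vapply(groupB$aligned_W, function(w) w[s, m], 0)
      degenerate <- stats::sd(xa) == 0 && stats::sd(xb) == 0
      if (degenerate) {
        tt <- list(statistic = NA_real_, p.value = NA_real_)
      } else if (nonparametric) {
        w <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
        tt <- list(statistic = unname(w$statistic), p.value = w$p.value)
      } else {
        t0 <- stats::t.test(xa, xb, var.equal = var_equal)
        tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        synergy = s, muscle = muscles[m],
        mean_A = mean(xa), sd_A = stats::sd(xa),
        mean_B = mean(xb), sd_B = stats::sd(xb),
        statistic = tt$statistic, p = tt$p.value,
        shapiro_A = shapiro_p(xa), shapiro_B = shapiro_p(xb)
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  attr(out, "test") <- if (nonparametric) "mann-whitney" else "t-test"
  out
}

#' Compare per-subject global VAF between groups
#'
#' Independent-samples t-test on per-subject global VAF at each synergy
#' count.
#'
#' @param vafsA,vafsB either numeric vectors (one VAF per subject, single k)
#'   or lists of numeric vectors named by k.
#' @param var_equal pooled-variance t-test if `TRUE` (default).
#' @return Data frame with one row per k: means, SDs, t, p.
#' @export
compare_vaf <- function(vafsA, vafsB, var_equal = TRUE) {
  if (!is.list(vafsA)) vafsA <- list(`1` = vafsA)
  if (!is.list(vafsB)) vafsB <- list(`1` = vafsB)
  ks <- intersect(names(vafsA), names(vafsB))
  if (length(ks) == 0L) stopf("no common k between the two groups")
  rows <- lapply(ks, function(kk) {
    xa <- vafsA[[kk]]; xb <- vafsB[[kk]]
    if (length(xa) < 2L || length(xb) < 2L) stopf("need >= 2 values per group")
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      tt <- list(statistic = NA_real_, p.value = if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else NA_real_)
    } else {
      t0 <- stats::t.test(xa, xb, var.equal = var_equal)
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    }
    data.frame(k = as.integer(kk), mean_A = mean(xa), sd_A = stats::sd(xa),
               mean_B = mean(xb), sd_B = stats::sd(xb),
               statistic = tt$statistic, p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Full two-group synergy comparison report
#'
#' Combines the cross-group correlation matrix of mean activation
#' coefficients (with similarity-band labels and the matched diagonal), the
#' per-(synergy, muscle) weight tests, and optional VAF tests.
#'
#' @param groupA,groupB `synergy_group` objects.
#' @param alpha significance level (default 0.05).
#' @param vafsA,vafsB optional per-subject global-VAF lists for
#'   [compare_vaf()].
#' @param ... passed to [compare_weights()].
#' @return An object of class `synergy_comparison`.
#' @export
compare_groups <- function(groupA, groupB, alpha = 0.05, vafsA = NULL,
                           vafsB = NULL, ...) {
  cors <- crossgroup_correlation(groupA$mean_H, groupB$mean_H)
  sim <- matrix(classify_similarity(as.vector(cors), warn_margin = 0),
                nrow(cors), ncol(cors), dimnames = dimnames(cors))
  # surface the boundary ambiguity once, for the matched diagonal
  diag_r <- diag(cors)
  invisible(tryCatch(classify_similarity(diag_r), warning = function(w) {
    warning(w); invokeRestart("muffleWarning")
  }))
  matched <- data.frame(
    synergy = seq_along(diag_r), r = diag_r,
    similarity = classify_similarity(diag_r, warn_margin = 0)
  )
  weight_tests <- compare_weights(groupA, groupB, alpha = alpha, ...)
  vaf_tests <- if (!is.null(vafsA) && !is.null(vafsB)) {
    compare_vaf(vafsA, vafsB)
  }
  structure(
    list(correlation_matrix = cors, similarity_class = sim,
         matched_pairs = matched, weight_tests = weight_tests,
         vaf_tests = vaf_tests, alpha = alpha,
         groups = c(groupA$group_label, groupB$group_label)),
    class = "synergy_comparison"
  )
}

#' @export
print.synergy_comparison <- function(x, ...) {
  cat(sprintf("Synergy comparison: %s vs %s (alpha = %g)\n",
              x$groups[1], x$groups[2], x$alpha))
  cat("\nCross-group correlation of mean activation coefficients:\n")
  print(round(x$correlation_matrix, 3))
  cat("\nMatched synergy pairs (diagonal):\n")
  print(transform(x$matched_pairs, r = round(r, 3)), row.names = FALSE)
  sig <- x$weight_tests[x$weight_tests$significant %in% TRUE, , drop = FALSE]
  cat(sprintf("\nWeight tests: %d of %d (synergy, muscle) cells significant\n",
              nrow(sig), nrow(x$weight_tests)))
  if (nrow(sig)) {
    print(within(sig, {
      p <- signif(p, 3); statistic <- round(statistic, 2)
      mean_A <- round(mean_A, 3); mean_B <- round(mean_B, 3)
      sd_A <- round(sd_A, 3); sd_B <- round(sd_B, 3)
      shapiro_A <- signif(shapiro_A, 2); shapiro_B <- signif(shapiro_B, 2)
    }), row.names = FALSE)
  }
  if (!is.null(x$vaf_tests)) {
    cat("\nPer-k global VAF tests:\n")
    print(transform(x$vaf_tests, p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}
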