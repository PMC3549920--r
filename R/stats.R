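#' Samples-by-features table
#'
#' The object every mass-univariate test and classifier consumes: one row
#' per (subject, run) sample, one column per feature (voxel, edge, or global
#' summary).
#'
#' @param values numeric `samples x features` matrix, no missing values.
#' @param labels per-sample group, `"control"` or `"patient"`.
#' @param subject_ids per-sample subject identifier.
#' @param feature_ids optional feature identifiers (default 1..F).
#' @param kind feature-kind label.
#' @return a `feature_table`.
#' @export
feature_table <- function(values, labels, subject_ids,
                          feature_ids = NULL, kind = "feature") {
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values))) {
    stop("feature table must not contain missing or non-finite values")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) stop("one label per sample required")
  if (length(unique(labels)) < 2L) stop("both groups must be represented")
  if (length(subject_ids) != nrow(values)) stop("one subject id per sample required")
  if (is.null(feature_ids)) feature_ids <- seq_len(ncol(values))
  structure(
    list(values = values, labels = labels,
         subject_ids = as.character(subject_ids),
         feature_ids = feature_ids, kind = kind),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d samples x %d features (%s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

# Vectorised pooled-variance two-sample t over the columns of a matrix.
pooled_ttest_matrix <- function(values, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- values[is_a, , drop = FALSE]
  x2 <- values[!is_a, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = df),
              ifelse(t == 0, 1, 0))
  # zero pooled variance: equal means -> t = 0, p = 1; unequal -> sentinel p = 0
  list(t = t, p = p, df = df,
       degenerate = se == 0 & diff != 0)
}

#' Mass-univariate two-sample t-test
#'
#' Pooled-variance two-sample t per feature, first group label minus second
#' (alphabetical order: control minus patient), two-sided p against Student
#' with `n1 + n2 - 2` degrees of freedom. Features with zero pooled variance
#' get `t = 0, p = 1` when the group means agree, and a flagged sentinel
#' `p = 0` otherwise.
#'
#' @param table a [feature_table()].
#' @return a `stats_result`: `t`, `p`, `df`, `degenerate` flags,
#'   `feature_ids`, `kind`.
#' @export
two_sample_ttest <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  groups <- sort(unique(table$labels))
  if (length(groups) != 2L) stop("exactly two groups required")
  res <- pooled_ttest_matrix(table$values, table$labels == groups[1])
  structure(
    list(t = res$t, p = res$p, df = res$df, degenerate = res$degenerate,
         groups = groups, feature_ids = table$feature_ids,
         kind = table$kind),
    class = "stats_result"
  )
}

#' Benjamini--Hochberg FDR selection
#'
#' Step-up selection at level `alpha`: all features whose BH-adjusted
#' p-value is at most `alpha` (equivalently, all features with `p` at or
#' below the largest `p(k) <= k alpha / N`).
#'
#' @param pvalues vector of p-values in `[0, 1]`.
#' @param alpha target false-discovery rate, in `(0, 1)`.
#' @return logical mask over features.
#' @export
fdr_select <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
            alpha > 0, alpha < 1)
  stats::p.adjust(pvalues, method = "BH") <= alpha
}

#' Bonferroni selection
#'
#' Selects features with `p <= alpha / N`, `N` the number of finite
#' p-values.
#'
#' @inheritParams fdr_select
#' @return logical mask over features.
#' @export
bonferroni_select <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
            alpha > 0, alpha < 1)
  n <- sum(is.finite(pvalues))
  pvalues <= alpha / n
}

#' Top-k features by p-value
#'
#' Feature positions of the `k` smallest p-values; ties are broken by
#' ascending feature position so rankings are reproducible.
#'
#' @param pvalues vector of p-values.
#' @param k number of features to keep, `1 <= k <= length(pvalues)`.
#' @return integer vector of length `k`.
#' @export
rank_topk <- function(pvalues, k) {
  n <- length(pvalues)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  order(pvalues, seq_len(n))[seq_len(k)]
}

#' Selection stability across folds
#'
#' Fraction of features common to *all* top-k sets: the size of the overall
#' intersection divided by `k`.
#'
#' @param topk_sets list (length >= 2) of feature-id vectors, each of size
#'   `k`.
#' @param k the selection size.
#' @return scalar in `[0, 1]`.
#' @export
stability <- function(topk_sets, k) {
  if (length(topk_sets) < 2L) stop("need at least 2 sets")
  sizes <- vapply(topk_sets, length, integer(1))
  if (any(sizes != k)) stop("all sets must have size k = ", k)
  length(Reduce(intersect, topk_sets)) / k
}

#' Motion-confound check
#'
#' Correlates every feature with a per-sample motion summary, converts each
#' correlation to a two-sided p-value through the t transform
#' `t = r sqrt((n-2)/(1-r^2))`, and applies FDR selection at `alpha`. An
#' empty selection mask indicates no detectable motion leakage into the
#' features.
#'
#' @param table a [feature_table()].
#' @param motion_summary numeric vector, one value per sample (nonconstant).
#' @param alpha FDR level (default 0.05).
#' @return list with `correlation`, `p`, `fdr_mask`, `alpha`.
#' @export
motion_confound_check <- function(table, motion_summary, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  m <- as.numeric(motion_summary)
  if (length(m) != nrow(table$values)) {
    stop("motion summary must have one value per sample")
  }
  if (stats::sd(m) == 0) stop("motion summary is constant")
  n <- length(m)
  mz <- (m - mean(m)) / stats::sd(m)
  vz <- scale(table$values) # constant features -> NaN columns
  r <- as.vector(crossprod(vz, mz)) / (n - 1)
  r[!is.finite(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(correlation = r, p = p, fdr_mask = fdr_select(p, alpha), alpha = alpha)
}

#' Non-parametric between-group test
#'
#' Two-sided Wilcoxon rank-sum (Mann--Whitney) test on one value per
#' subject, with Bonferroni correction over the number of connectivity
#' measures tested. Ties are handled by midranks (normal approximation);
#' all-identical data give `p = 1`. A signed-rank variant is available for
#' genuinely paired designs.
#'
#' @param per_subject_values numeric vector, one value per subject.
#' @param labels group label per subject (two groups, >= 2 each).
#' @param n_comparisons Bonferroni divisor (number of measures tested).
#' @param paired use the signed-rank test (requires equal group sizes and a
#'   meaningful pairing order).
#' @return corrected p-value (capped at 1).
#' @export
ranksum_group_test <- function(per_subject_values, labels, n_comparisons = 1L,
                               paired = FALSE) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("exactly two groups required")
  x <- per_subject_values[labels == groups[1]]
  y <- per_subject_values[labels == groups[2]]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 subjects per group")
  if (stats::sd(per_subject_values) == 0) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = !paired)$p.value
  )
  min(1, p * n_comparisons)
}
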