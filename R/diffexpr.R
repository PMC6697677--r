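#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the identical sorted value multiset:
#' the i-th order statistic of each column is replaced by the mean of the i-th
#' order statistics across columns. Rank assignment for tied values is
#' order-based (first occurrence first), which preserves the multiset property
#' exactly; ties are measure-zero for continuous intensities. Feature order is
#' preserved.
#'
#' @param expr A wide expression tibble: first column `feature_id`, remaining
#'   columns one per sample, all intensities positive.
#' @return A tibble of the same shape with normalized intensities.
#' @export
#' @examples
#' x <- tibble::tibble(feature_id = c("a", "b", "c"),
#'                     s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' quantile_normalize(x)  # both columns become (2.5, 3.5, 4.5)
quantile_normalize <- function(expr) {
  m <- expr_values(expr)
  if (ncol(m) < 2) {
    warn("Only one sample column: quantile normalization returns the input unchanged.")
    return(as_tibble(expr))
  }
  if (any(m <= 0)) abort("All intensities must be positive before normalization.")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  res <- as_tibble(expr)
  res[, -1] <- as_tibble(out)
  res
}

# feature_id column -> rownames-free numeric matrix of sample columns
expr_values <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# 0/1 selection matrix (n x choose(n, n1)) of all case-assignments
mw_selection_matrix <- function(n, n1) {
  combos <- combn(n, n1)
  sel <- matrix(0, nrow = n, ncol = ncol(combos))
  sel[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n1))] <- 1
  sel
}

# Exact two-sided Mann-Whitney p-values, one per row of `mat`.
# Enumerates every C(n, n1) assignment of the (mid)ranks to the case group;
# two-sided p is the doubled smaller tail, capped at 1 (equal-tail
# convention). Ties enter through midranks, so the null distribution is
# conditional on each row's own tie pattern.
mw_exact_rows <- function(mat, case_idx, control_idx) {
  n1 <- length(case_idx)
  n <- n1 + length(control_idx)
  mat <- mat[, c(case_idx, control_idx), drop = FALSE]
  ranks <- t(apply(mat, 1, rank))
  if (nrow(mat) == 1) ranks <- matrix(ranks, nrow = 1)
  sel <- mw_selection_matrix(n, n1)
  sums <- ranks %*% sel
  obs <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  eps <- 1e-8
  lo <- rowMeans(sums <= obs + eps)
  hi <- rowMeans(sums >= obs - eps)
  pmin(1, 2 * pmin(lo, hi))
}

# Normal approximation with midranks and tie correction (no continuity
# correction), used when the exact enumeration is not feasible.
mw_normal_rows <- function(mat, case_idx, control_idx) {
  n1 <- length(case_idx)
  n2 <- length(control_idx)
  n <- n1 + n2
  mat <- mat[, c(case_idx, control_idx), drop = FALSE]
  ranks <- t(apply(mat, 1, rank))
  if (nrow(mat) == 1) ranks <- matrix(ranks, nrow = 1)
  w <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tie_term <- apply(mat, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  p <- rep(1, nrow(mat))
  ok <- sigma2 > 0
  z <- (w[ok] - mu) / sqrt(sigma2[ok])
  p[ok] <- pmin(1, 2 * pnorm(-abs(z)))
  p
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes the two-sided Mann-Whitney (Wilcoxon rank-sum) p-value by complete
#' enumeration of all `choose(n1 + n2, n1)` group assignments when the total
#' sample size is at most 12 — the regime of a 4 vs 4 microarray comparison,
#' where the attainable p-values form a small finite set with minimum
#' `2/choose(8, 4) = 2/70`. Ties are handled by enumerating midrank
#' statistics, so the reference distribution is conditional on the observed
#' tie pattern. For larger samples a normal approximation with midranks and
#' tie correction is used. The two-sided p-value is the smaller tail
#' probability doubled and capped at 1.
#'
#' @param case_values,control_values Numeric vectors, each of length >= 2.
#' @return A single p-value in (0, 1]. When all values are tied across both
#'   groups the test carries no evidence and returns 1.
#' @export
#' @examples
#' mann_whitney_exact(c(8, 9, 10, 11), c(1, 2, 3, 4))  # 2/70, complete separation
#' mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))          # 1
mann_whitney_exact <- function(case_values, control_values) {
  case_values <- as.numeric(case_values)
  control_values <- as.numeric(control_values)
  if (length(case_values) < 2 || length(control_values) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  if (anyNA(case_values) || anyNA(control_values)) {
    abort("Missing values are not supported.")
  }
  mat <- matrix(c(case_values, control_values), nrow = 1)
  n1 <- length(case_values)
  idx_case <- seq_len(n1)
  idx_ctrl <- n1 + seq_along(control_values)
  if (length(case_values) + length(control_values) <= 12) {
    mw_exact_rows(mat, idx_case, idx_ctrl)
  } else {
    mw_normal_rows(mat, idx_case, idx_ctrl)
  }
}

#' Call differential expression with a fold-change + Mann-Whitney rule
#'
#' Applies the two-criterion dysregulation rule per feature: fold change
#' (case group mean over control group mean, on the normalized linear scale)
#' at least `fc_threshold` or at most its reciprocal, *and* exact two-sided
#' Mann-Whitney p-value at most `p_threshold`. Benjamini-Hochberg FDR over all
#' features in the matrix is reported for transparency but plays no part in
#' the selection, mirroring the raw-p + fold-change convention of small-n
#' microarray studies. At 4 vs 4 the exact test's smallest attainable p is
#' 2/70 ≈ 0.029, so any call at `p <= 0.05` requires (near-)complete group
#' separation.
#'
#' @param expr Wide expression tibble (first column `feature_id`).
#' @param samples Sample sheet: tibble with `sample_id` matching the expression
#'   columns and `group` in `{"case", "control"}`.
#' @param fc_threshold Fold-change threshold (>= 1; default 1.5).
#' @param p_threshold P-value threshold (default 0.05).
#' @param log_scale_fc If `TRUE`, compute the fold change as the ratio of
#'   geometric (log-scale) group means instead of arithmetic means.
#' @return A tibble (one row per called feature) with columns `feature_id`,
#'   `fold_change`, `p_value`, `fdr`, `direction` (`"up"`, `"down"`,
#'   `"none"`). Features whose control mean is not positive are excluded with
#'   a warning.
#' @export
call_de <- function(expr, samples, fc_threshold = 1.5, p_threshold = 0.05,
                    log_scale_fc = FALSE) {
  if (fc_threshold < 1) abort("`fc_threshold` must be >= 1.")
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` needs columns `sample_id` and `group`.")
  }
  if (!all(samples$group %in% c("case", "control"))) {
    abort("`samples$group` must be 'case' or 'control'.")
  }
  sample_cols <- names(expr)[-1]
  missing <- setdiff(samples$sample_id, sample_cols)
  if (length(missing)) {
    abort(sprintf("Sample sheet names absent from the matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  m <- expr_values(expr)[, samples$sample_id, drop = FALSE]
  case_idx <- which(samples$group == "case")
  ctrl_idx <- which(samples$group == "control")
  if (length(case_idx) < 2 || length(ctrl_idx) < 2) {
    abort("Each group needs at least 2 samples.")
  }

  ctrl_mean <- rowMeans(m[, ctrl_idx, drop = FALSE])
  case_mean <- rowMeans(m[, case_idx, drop = FALSE])
  qc_fail <- ctrl_mean <= 0 | case_mean <= 0
  if (any(qc_fail)) {
    warn(sprintf("%d feature(s) with nonpositive group mean excluded from calling.",
                 sum(qc_fail)))
  }
  keep <- which(!qc_fail)
  mk <- m[keep, , drop = FALSE]

  fc <- if (log_scale_fc) {
    2^(rowMeans(log2(mk[, case_idx, drop = FALSE])) -
         rowMeans(log2(mk[, ctrl_idx, drop = FALSE])))
  } else {
    case_mean[keep] / ctrl_mean[keep]
  }
  p <- if (length(case_idx) + length(ctrl_idx) <= 12) {
    mw_exact_rows(mk, case_idx, ctrl_idx)
  } else {
    mw_normal_rows(mk, case_idx, ctrl_idx)
  }
  fdr <- p.adjust(p, method = "BH")
  direction <- dplyr::case_when(
    p <= p_threshold & fc >= fc_threshold ~ "up",
    p <= p_threshold & fc <= 1 / fc_threshold ~ "down",
    .default = "none"
  )
  tibble(
    feature_id = expr[[1]][keep],
    fold_change = fc,
    p_value = p,
    fdr = fdr,
    direction = direction
  )
}

#' Cross-time-point specificity from two differential-expression tables
#'
#' A feature counts as dysregulated at a time point if its direction there is
#' not `"none"`. Specificity is the percentage of distinct dysregulated
#' features that are dysregulated at exactly one of the two time points.
#'
#' @param de_time1,de_time2 DE tables from [call_de()] over the same feature
#'   universe.
#' @return A one-row tibble: `n_time1`, `n_time2`, `n_both`, `n_distinct`,
#'   `n_specific`, `fraction_specific` (percent).
#' @seealso [specificity_from_counts()] for the pure count arithmetic.
#' @export
time_specificity <- function(de_time1, de_time2) {
  u1 <- de_time1$feature_id
  u2 <- de_time2$feature_id
  if (!setequal(u1, u2)) {
    only1 <- setdiff(u1, u2)
    only2 <- setdiff(u2, u1)
    abort(sprintf(
      "DE tables cover different feature universes: %d only in time 1 (e.g. %s), %d only in time 2 (e.g. %s).",
      length(only1), paste(head(only1, 3), collapse = ", "),
      length(only2), paste(head(only2, 3), collapse = ", ")))
  }
  d1 <- de_time1$feature_id[de_time1$direction != "none"]
  d2 <- de_time2$feature_id[de_time2$direction != "none"]
  specificity_from_counts(length(d1), length(d2), length(intersect(d1, d2)))
}

#' Time-specificity arithmetic from per-time counts
#'
#' @param n_time1,n_time2 Number of dysregulated features at each time point.
#' @param n_both Number dysregulated at both.
#' @return A one-row tibble with `n_distinct = n_time1 + n_time2 - n_both`,
#'   `n_specific = n_distinct - n_both`, and `fraction_specific` as a percent
#'   (`NA` when no feature is dysregulated at either time).
#' @export
#' @examples
#' specificity_from_counts(101, 12, 2)  # 109/111 = 98.2%
specificity_from_counts <- function(n_time1, n_time2, n_both) {
  if (n_both > min(n_time1, n_time2)) {
    abort("`n_both` cannot exceed either per-time count.")
  }
  if (any(c(n_time1, n_time2, n_both) < 0)) abort("Counts must be nonnegative.")
  n_distinct <- n_time1 + n_time2 - n_both
  n_specific <- n_distinct - n_both
  tibble(
    n_time1 = n_time1, n_time2 = n_time2, n_both = n_both,
    n_distinct = n_distinct, n_specific = n_specific,
    fraction_specific = if (n_distinct > 0) 100 * n_specific / n_distinct else NA_real_
  )
}
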