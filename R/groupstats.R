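#' Independent-samples pooled-variance t-test
#'
#' Two-sided Student t-test with pooled variance; df = n1 + n2 - 2.
#'
#' @param a,b Numeric vectors (each length >= 2, finite).
#' @return List with `t`, `df`, `p`, group means and SDs.
#' @export
ttest_ind <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::var(a) + stats::var(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                mean_a = mean(a), mean_b = mean(b),
                sd_a = stats::sd(a), sd_b = stats::sd(b)))
  }
  if (stats::var(a) + stats::var(b) == 0) stop("zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       sd_a = stats::sd(a), sd_b = stats::sd(b))
}

#' Wilcoxon rank-sum test (demographics utility)
#'
#' Same contract as [ttest_ind()]: exact null distribution for small
#' samples (both n <= 25, no ties), normal approximation otherwise.
#'
#' @param a,b Numeric vectors.
#' @return List with `statistic` (W), `p`, group medians.
#' @export
wilcoxon_ind <- function(a, b) {
  exact <- length(a) <= 25 && length(b) <= 25
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       median_a = stats::median(a), median_b = stats::median(b))
}

#' Cohen's d from a t statistic
#'
#' Equal-n conversion `d = 2|t| / sqrt(df)`, the form that reproduces the
#' printed effect sizes of two-group topology comparisons at df = n1+n2-2.
#' For raw samples, [cohens_d_pooled()] gives the pooled-SD version.
#'
#' @param t t statistic.
#' @param df Degrees of freedom (> 0).
#' @return Effect size d (>= 0).
#' @export
cohens_d_from_t <- function(t, df) {
  if (df <= 0) stop("df must be positive")
  2 * abs(t) / sqrt(df)
}

#' Pooled-SD Cohen's d from raw samples
#'
#' @param a,b Numeric vectors.
#' @return Signed effect size (mean(a) - mean(b)) / pooled SD.
#' @export
cohens_d_pooled <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  (mean(a) - mean(b)) / sp
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement;
#' order-preserving and never smaller than the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Band-wise, sparsity-wise group comparison of a topology metric
#'
#' Pooled t-test at every sparsity level with BH correction across the
#' grid (the FDR family is all sparsity levels within one band x metric),
#' plus Cohen's d per level.
#'
#' @param mat_a,mat_b Numeric matrices, subjects x sparsity levels, one
#'   metric each; columns must align on the same grid.
#' @param grid Sparsity levels labelling the columns.
#' @param band,metric Identifiers copied into the output.
#' @return `data.frame` with one row per sparsity level: t, df, p, p_fdr,
#'   cohens_d, group means and SDs.
#' @export
compare_curves <- function(mat_a, mat_b, grid = sparsity_grid(),
                           band = NA_character_, metric = NA_character_) {
  stopifnot(ncol(mat_a) == ncol(mat_b), ncol(mat_a) == length(grid))
  rows <- lapply(seq_along(grid), function(s) {
    tt <- ttest_ind(mat_a[, s], mat_b[, s])
    data.frame(band = band, metric = metric, sparsity = grid[s],
               t = tt$t, df = tt$df, p = tt$p,
               cohens_d = cohens_d_from_t(tt$t, tt$df),
               mean_a = tt$mean_a, mean_b = tt$mean_b,
               sd_a = tt$sd_a, sd_b = tt$sd_b)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p)
  out[, c("band", "metric", "sparsity", "t", "df", "p", "p_fdr",
          "cohens_d", "mean_a", "mean_b", "sd_a", "sd_b")]
}

#' Average a metric over the FDR-significant sparsity levels
#'
#' Identifies grid levels where the BH-adjusted comparison is significant,
#' averages each subject's metric over that set, and re-runs the t-test
#' and effect size on the averaged values. With no significant level the
#' significant set is empty and no comparison is returned.
#'
#' @inheritParams compare_curves
#' @param alpha Significance level on the BH-adjusted p-values.
#' @return List with `significant` (grid values), `per_level` (the
#'   [compare_curves()] table), `values_a`/`values_b` (per-subject
#'   averages) and `comparison` (t/df/p/cohens_d on the averages, or
#'   `NULL` when the set is empty).
#' @export
average_significant <- function(mat_a, mat_b, grid = sparsity_grid(),
                                alpha = 0.05, band = NA_character_,
                                metric = NA_character_) {
  per_level <- compare_curves(mat_a, mat_b, grid, band, metric)
  sig <- grid[per_level$p_fdr < alpha]
  if (length(sig) == 0) {
    return(list(significant = numeric(0), per_level = per_level,
                values_a = NULL, values_b = NULL, comparison = NULL))
  }
  idx <- match(sig, grid)
  va <- rowMeans(mat_a[, idx, drop = FALSE])
  vb <- rowMeans(mat_b[, idx, drop = FALSE])
  tt <- ttest_ind(va, vb)
  list(significant = sig, per_level = per_level,
       values_a = va, values_b = vb,
       comparison = data.frame(band = band, metric = metric,
                               t = tt$t, df = tt$df, p = tt$p,
                               cohens_d = cohens_d_from_t(tt$t, tt$df),
                               mean_a = tt$mean_a, mean_b = tt$mean_b))
}
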