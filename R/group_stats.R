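group_comparison <- function(comparison, test, statistic, p_value, n1, n2) {
  data.frame(comparison = comparison, test = test, statistic = statistic,
             p_value = p_value, p_adjusted = NA_real_, n1 = n1, n2 = n2,
             stringsAsFactors = FALSE)
}

#' Two-group prevalence comparison
#'
#' Two-proportion chi-square test without continuity correction, used for
#' prevalence (fraction of subjects in whom an enzyme is detected) between
#' cohorts.
#'
#' @param k1,n1 detected count and group size in group 1.
#' @param k2,n2 detected count and group size in group 2.
#' @param comparison optional label.
#' @return one-row comparison data frame (statistic = chi-square, raw p;
#'   `p_adjusted` is filled by [adjust_p()]).
#' @export
prevalence_test <- function(k1, n1, k2, n2, comparison = "") {
  if (n1 < 1 || n2 < 1) stopf("group sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stopf("counts must satisfy 0 <= k <= n")
  ht <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
  group_comparison(comparison, "two-proportion chi-square",
                   unname(ht$statistic), ht$p.value, n1, n2)
}

#' Two-group abundance comparison (Mann-Whitney)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the normal
#' approximation, tie correction and continuity correction, used for
#' comparing RPKM distributions between cohorts.
#'
#' @param x,y numeric values of group 1 and group 2.
#' @param comparison optional label.
#' @return one-row comparison data frame (statistic = U of group 1).
#' @export
abundance_test <- function(x, y, comparison = "") {
  if (length(x) < 1 || length(y) < 1) stopf("both groups need >= 1 value")
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE, correct = TRUE))
  group_comparison(comparison, "Mann-Whitney", unname(ht$statistic),
                   ht$p.value, length(x), length(y))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of comparisons
#' (the comparisons of one figure panel in cohort analyses).
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param method adjustment method (passed to [stats::p.adjust()]).
#' @return adjusted p-values, order-preserving.
#' @export
adjust_p <- function(pvals, method = "BH") {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = method)
}

#' Spearman rank correlation
#'
#' Spearman correlation with average ranks for ties; two-sided p-value from
#' the t approximation. Constant input vectors leave the correlation
#' undefined: `NA` is returned with a warning.
#'
#' @param x,y paired numeric vectors (>= 3 pairs).
#' @return list with `estimate` (rho), `p_value`, `n`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warnf("constant vector: Spearman correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(rank(x), rank(y))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (is.finite(tstat)) 2 * pt(-abs(tstat), df = n - 2) else 0
  list(estimate = r, p_value = min(1, p), n = n)
}

#' Relative abundance of a target metabolite
#'
#' For each sample, `100 * sum(target metabolites) / sum(all metabolites)`:
#' the percent abundance of the target relative to all observed metabolites
#' (the normalization used for fecal oxalate). Samples whose total abundance
#' is zero are excluded with a warning. Optionally returns `log10` values
#' with zero shares mapped to `NA`.
#'
#' @param tbl numeric matrix or data frame, samples in rows, metabolites in
#'   columns (non-negative).
#' @param targets column name(s) of the target metabolite(s).
#' @param log10_transform return log10 of the percentage, zeros as `NA`.
#' @return named numeric vector of per-sample percent abundance.
#' @export
metabolite_relative_abundance <- function(tbl, targets,
                                          log10_transform = FALSE) {
  tbl <- as.matrix(tbl)
  if (any(tbl < 0)) stopf("metabolite abundances must be >= 0")
  bad <- setdiff(targets, colnames(tbl))
  if (length(bad)) stopf("unknown metabolite(s): %s", paste(bad, collapse = ", "))
  totals <- rowSums(tbl)
  zero <- totals == 0
  if (any(zero)) {
    warnf("excluding %d sample(s) with zero total metabolite abundance",
          sum(zero))
    tbl <- tbl[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  share <- 100 * rowSums(tbl[, targets, drop = FALSE]) / totals
  if (log10_transform) {
    share[share == 0] <- NA_real_
    share <- log10(share)
  }
  share
}
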