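#' Group summary statistics for a scalar endpoint
#'
#' Bundles per-group means, standard deviations and sample sizes, the form in
#' which clinical papers print group comparisons. All summary-based tests in
#' this package ([two_sample_t()], [cohens_d_pooled()]) start from this object,
#' so printed tables can be re-analysed without raw data.
#'
#' @param mean1,sd1,n1 Mean, standard deviation and size of the first group.
#' @param mean2,sd2,n2 Mean, standard deviation and size of the second group.
#' @return A `summary_stats` object (a one-row tibble).
#' @examples
#' summary_stats(28.55, 16.97, 30, 20.63, 7.06, 23)
#' @export
summary_stats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(is.numeric(mean1), is.numeric(mean2))
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  out <- tibble::tibble(
    mean1 = mean1, sd1 = sd1, n1 = as.integer(n1),
    mean2 = mean2, sd2 = sd2, n2 = as.integer(n2)
  )
  class(out) <- c("summary_stats", class(out))
  out
}

#' Unpaired two-sample t-test from group summaries
#'
#' Classical two-sided t-test computed from group means, SDs and sizes. The
#' `pooled` variant assumes equal variances (df = n1 + n2 - 2); the `welch`
#' variant uses the Welch-Satterthwaite approximation. The sign of `t` is
#' mean1 - mean2.
#'
#' @param summary A [summary_stats()] object.
#' @param variant `"pooled"` (equal variance) or `"welch"`.
#' @return A tibble with columns `t`, `df`, `p`, `mean_diff`, `variant`.
#' @examples
#' # first-cycle N3 power, affected vs control
#' two_sample_t(summary_stats(28.55, 16.97, 30, 20.63, 7.06, 23))
#' @export
two_sample_t <- function(summary, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  s <- summary
  diff <- s$mean1 - s$mean2
  v1 <- s$sd1^2
  v2 <- s$sd2^2
  if (variant == "pooled") {
    df <- s$n1 + s$n2 - 2
    sp2 <- ((s$n1 - 1) * v1 + (s$n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / s$n1 + 1 / s$n2))
  } else {
    a <- v1 / s$n1
    b <- v2 / s$n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (s$n1 - 1) + b^2 / (s$n2 - 1))
  }
  if (se == 0) {
    # zero variance in both groups: identical data give t = 0, unequal means
    # are infinitely separated
    t <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(t = t, df = df, p = p, mean_diff = diff, variant = variant)
}

#' Cohen's d from group summaries (pooled SD)
#'
#' d = (mean1 - mean2) / s_pooled with
#' s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2).
#'
#' @inheritParams two_sample_t
#' @return The standardized mean difference (a single number).
#' @examples
#' cohens_d_pooled(summary_stats(22.90, 12.65, 30, 15.77, 5.22, 23))
#' @export
cohens_d_pooled <- function(summary) {
  s <- summary
  sp2 <- ((s$n1 - 1) * s$sd1^2 + (s$n2 - 1) * s$sd2^2) / (s$n1 + s$n2 - 2)
  if (sp2 == 0) stop("pooled SD is zero; Cohen's d undefined")
  (s$mean1 - s$mean2) / sqrt(sp2)
}

#' Chi-squared test of independence with Yates continuity correction (2x2)
#'
#' chi2 = sum((|O - E| - 0.5)^2 / E), with the correction capped so that
#' |O - E| - 0.5 never goes negative. df = 1.
#'
#' @param table_2x2 A 2x2 matrix of counts (groups x categories).
#' @return A tibble with `chi2`, `df`, `p`.
#' @examples
#' yates_chi2(matrix(c(21, 12, 9, 11), nrow = 2))  # sex by group
#' @export
yates_chi2 <- function(table_2x2) {
  x <- as.matrix(table_2x2)
  if (!all(dim(x) == c(2, 2))) stop("expected a 2x2 table")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("all row and column margins must be positive")
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  dev <- pmax(abs(x - expected) - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  tibble::tibble(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Bonferroni adjustment for a family of comparisons
#'
#' p_adj = min(1, m * p). Also reports the per-test threshold alpha / m used
#' when a fixed family-wise alpha is controlled (e.g. five clinical
#' correlations at alpha = 0.05 give a per-test threshold of 0.01).
#'
#' @param p Vector of raw p-values.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @param alpha Family-wise significance level.
#' @return A tibble with `p`, `p_adj`, `significant` and the `threshold`
#'   (alpha / m) attached as an attribute.
#' @export
pairwise_bonferroni <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- tibble::tibble(
    p = p,
    p_adj = pmin(1, m * p),
    significant = pmin(1, m * p) < alpha
  )
  attr(out, "threshold") <- alpha / m
  attr(out, "m") <- m
  out
}
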