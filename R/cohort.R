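# Shapiro-Wilk normality decision at alpha; degenerate samples (constant,
# or n outside the test's 3..5000 support) are treated as non-normal.
is_normal_sample <- function(x, alpha) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Summarize a feature sample
#'
#' Chooses the summary form by a Shapiro-Wilk normality decision at
#' `alpha`: normally distributed samples are reported as mean +/- SD,
#' non-normal ones as median (IQR). Samples of fewer than 3 values get a
#' median summary without a normality decision, flagged.
#'
#' @param x Numeric sample (`NA` dropped).
#' @param alpha Significance level for the normality test.
#' @return An object of class `feature_summary` with `n`, `normal`,
#'   `form`, the location/spread values and a formatted `label`.
#' @examples
#' summarize_feature(rnorm(30, 66, 11))
#' @export
summarize_feature <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    return(structure(list(n = 0L, normal = NA, form = "none",
                          label = "N/A", flag = "empty"),
                     class = "feature_summary"))
  }
  if (n < 3) {
    q <- pct_quantile(x, c(25, 50, 75))
    return(structure(
      list(n = n, normal = NA, form = "median_iqr",
           median = q[2], q1 = q[1], q3 = q[3],
           label = sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3]),
           flag = "too_few_for_normality"),
      class = "feature_summary"))
  }
  normal <- is_normal_sample(x, alpha)
  if (normal) {
    m <- mean(x)
    s <- stats::sd(x)
    structure(list(n = n, normal = TRUE, form = "mean_sd",
                   mean = m, sd = s,
                   label = sprintf("%.3g +/- %.3g", m, s), flag = ""),
              class = "feature_summary")
  } else {
    q <- pct_quantile(x, c(25, 50, 75))
    structure(list(n = n, normal = FALSE, form = "median_iqr",
                   median = q[2], q1 = q[1], q3 = q[3],
                   label = sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3]),
                   flag = ""),
              class = "feature_summary")
  }
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("<feature_summary> n=%d %s [%s]\n", x$n, x$label, x$form))
  invisible(x)
}

new_group_comparison <- function(feature, labels, summaries, test_used,
                                 statistic, p_value, alpha,
                                 n_excluded = 0L, note = "") {
  structure(
    list(feature = feature, labels = labels, summaries = summaries,
         test_used = test_used, statistic = unname(statistic),
         p_value = unname(p_value),
         significant = !is.na(p_value) && p_value < alpha,
         alpha = alpha, n_excluded = n_excluded, note = note),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s | %s | stat %.4g, p %.4g%s\n",
              x$feature, x$labels[1], x$labels[2], x$test_used,
              x$statistic, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare a feature between two independent groups
#'
#' Test choice follows the joint normality of the two samples
#' (Shapiro-Wilk at `alpha`): both normal, Student's t-test (pooled
#' variance); otherwise the Mann-Whitney U test (normal approximation
#' with tie correction, no continuity correction; switch with `exact`).
#' Undefined feature values are excluded and counted.
#'
#' @param a,b Numeric samples.
#' @param alpha Significance level.
#' @param feature,labels Labels carried into the result.
#' @param exact Use the exact Mann-Whitney distribution (small, tie-free
#'   samples only).
#' @param alternative Alternative hypothesis, as in [stats::wilcox.test()].
#' @return A `group_comparison` object.
#' @examples
#' compare_unpaired(rnorm(20), rnorm(20, 1))
#' @export
compare_unpaired <- function(a, b, alpha = 0.05, feature = "feature",
                             labels = c("A", "B"), exact = FALSE,
                             alternative = "two.sided") {
  n_excluded <- sum(is.na(a)) + sum(is.na(b))
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("comparison_underpowered: each group needs at least 3 defined values",
         call. = FALSE)
  }
  both_normal <- is_normal_sample(a, alpha) && is_normal_sample(b, alpha)
  if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE, alternative = alternative)
    res <- new_group_comparison(feature, labels,
                                list(summarize_feature(a, alpha),
                                     summarize_feature(b, alpha)),
                                "t_test", tt$statistic, tt$p.value, alpha,
                                n_excluded)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = FALSE,
                         alternative = alternative))
    res <- new_group_comparison(feature, labels,
                                list(summarize_feature(a, alpha),
                                     summarize_feature(b, alpha)),
                                "mann_whitney", wt$statistic, wt$p.value,
                                alpha, n_excluded)
  }
  res
}

#' Compare paired pre/post measurements
#'
#' For repeated measurements (e.g. before and after angioplasty at the
#' same site), the test follows the normality of the paired differences:
#' paired t-test when normal, Wilcoxon signed-rank otherwise (normal
#' approximation, zero differences dropped before ranking, tie ranks
#' averaged). Pairs with an undefined member are excluded and counted.
#' When every difference is zero the null center is returned directly
#' (statistic 0, p = 1).
#'
#' @param pre,post Numeric samples matched by position (same patient).
#' @inheritParams compare_unpaired
#' @return A `group_comparison` object.
#' @export
compare_paired <- function(pre, post, alpha = 0.05, feature = "feature",
                           labels = c("pre", "post"), exact = FALSE,
                           alternative = "two.sided") {
  stopifnot(length(pre) == length(post))
  ok <- !is.na(pre) & !is.na(post)
  n_excluded <- sum(!ok)
  pre <- pre[ok]
  post <- post[ok]
  if (length(pre) < 3) {
    stop("comparison_underpowered: fewer than 3 complete pairs",
         call. = FALSE)
  }
  d <- post - pre
  summaries <- list(summarize_feature(pre, alpha),
                    summarize_feature(post, alpha))
  if (all(d == 0)) {
    return(new_group_comparison(feature, labels, summaries,
                                "wilcoxon_signed_rank", 0, 1, alpha,
                                n_excluded, note = "all_differences_zero"))
  }
  if (is_normal_sample(d, alpha)) {
    tt <- stats::t.test(post, pre, paired = TRUE,
                        alternative = alternative)
    new_group_comparison(feature, labels, summaries, "paired_t",
                         tt$statistic, tt$p.value, alpha, n_excluded)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = exact,
                         correct = FALSE, alternative = alternative))
    new_group_comparison(feature, labels, summaries,
                         "wilcoxon_signed_rank", wt$statistic, wt$p.value,
                         alpha, n_excluded)
  }
}

#' Compare categorical distributions between two groups
#'
#' Pearson chi-square test on the category counts, without continuity
#' correction.
#'
#' @param counts_a,counts_b Non-negative integer count vectors over the
#'   same categories.
#' @inheritParams compare_unpaired
#' @return A `group_comparison` object.
#' @examples
#' # male/female balance between two groups
#' compare_categorical(c(male = 25, female = 22), c(male = 46, female = 26))
#' @export
compare_categorical <- function(counts_a, counts_b, alpha = 0.05,
                                feature = "category",
                                labels = c("A", "B")) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 2)
  if (any(counts_a < 0) || any(counts_b < 0) ||
      any(counts_a != round(counts_a)) || any(counts_b != round(counts_b))) {
    stop("counts_invalid: counts must be non-negative integers",
         call. = FALSE)
  }
  tab <- rbind(counts_a, counts_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("counts_degenerate: zero marginal in the contingency table",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_group_comparison(feature, labels, list(counts_a, counts_b),
                       "chi_square", ct$statistic, ct$p.value, alpha)
}
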