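test_that("summary form follows the normality of the sample", {
  # bell-shaped samples mostly get mean +/- SD
  forms <- vapply(1:40, function(s) {
    set.seed(s)
    summarize_feature(rnorm(100, 66, 11))$form
  }, character(1))
  expect_gte(mean(forms == "mean_sd"), 0.9)

  # heavily skewed samples get median (IQR)
  forms <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    summarize_feature(rlnorm(100, 0, 1))$form
  }, character(1))
  expect_gte(mean(forms == "median_iqr"), 0.9)

  # degenerate cases
  const <- summarize_feature(rep(5, 10))
  expect_equal(const$form, "median_iqr")
  expect_equal(const$q3 - const$q1, 0)
  tiny <- summarize_feature(c(1, 2))
  expect_true(is.na(tiny$normal))
  expect_equal(tiny$flag, "too_few_for_normality")
})

test_that("identical samples give p = 1 under the rank test", {
  x <- exp(seq(0, 6, length.out = 12))   # skewed, so the rank test is used
  cmp <- compare_unpaired(x, x)
  expect_equal(cmp$test_used, "mann_whitney")
  expect_equal(cmp$p_value, 1)
  expect_false(cmp$significant)
})

test_that("test choice follows joint normality", {
  set.seed(2)
  a <- rnorm(50)
  b <- rnorm(50, 0.2)
  expect_equal(compare_unpaired(a, b)$test_used, "t_test")
  expect_equal(compare_unpaired(exp(a * 3), b)$test_used, "mann_whitney")
})

test_that("rank tests are invariant to strictly monotone transforms", {
  set.seed(3)
  a <- rlnorm(25, log(5), 0.4)
  b <- rlnorm(25, log(8), 0.4)
  p1 <- compare_unpaired(a, b)$p_value
  w1 <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  w2 <- suppressWarnings(wilcox.test(a^3, b^3, exact = FALSE,
                                     correct = FALSE))
  expect_equal(w1$p.value, w2$p.value, tolerance = 1e-12)
  expect_equal(compare_unpaired(a^3, b^3)$p_value, p1, tolerance = 1e-12)
})

test_that("undefined values are excluded and counted", {
  a <- c(rnorm(10), NA, NA)
  b <- rnorm(10)
  expect_equal(compare_unpaired(a, b)$n_excluded, 2)
  expect_error(compare_unpaired(c(1, 2, NA), rnorm(5)),
               "comparison_underpowered")
})

test_that("paired comparisons handle identity, NAs and direction", {
  pre <- c(5, 6, 7, 8, 9)
  same <- compare_paired(pre, pre)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$note, "all_differences_zero")

  post <- pre + c(NA, 1, 1, 2, 1)
  cmp <- compare_paired(pre, post)
  expect_equal(cmp$n_excluded, 1)
  expect_error(compare_paired(c(1, 2), c(2, 3)), "comparison_underpowered")

  # a genuine within-patient increase is detected
  set.seed(4)
  p0 <- rlnorm(30, log(0.01), 0.5)
  p1 <- p0 * exp(rnorm(30, log(2), 0.3))
  up <- compare_paired(p0, p1, alternative = "greater")
  expect_true(up$significant)
})

test_that("chi-square agrees with the closed form on all small 2x2 tables", {
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    n <- a + b + cc + d
    stat_hand <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    cmp <- compare_categorical(c(a, b), c(cc, d))
    expect_equal(cmp$statistic, stat_hand, tolerance = 1e-12)
    expect_equal(cmp$p_value, pchisq(stat_hand, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("chi-square contracts: identical proportions and degenerate input", {
  cmp <- compare_categorical(c(10, 10), c(20, 20))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_categorical(c(0, 0), c(1, 2)), "counts_degenerate")
  expect_error(compare_categorical(c(-1, 2), c(1, 2)), "counts_invalid")
})

make_feature_df <- function(groups, sites, n, access = "AVF", seed = 1,
                            phase = "none") {
  set.seed(seed)
  rows <- expand.grid(group = groups, site = sites, i = seq_len(n),
                      stringsAsFactors = FALSE)
  data.frame(
    patient_id = sprintf("P%s_%d", rows$group, rows$i),
    access_type = access, site = rows$site, group = rows$group,
    phase = phase,
    mean_peak = rlnorm(nrow(rows), log(0.3), 0.4),
    mean_valley = rlnorm(nrow(rows), log(0.05), 0.4),
    peak_valley_ratio = rlnorm(nrow(rows), log(5), 0.3),
    low_frequency_pct = runif(nrow(rows), 20, 70),
    stringsAsFactors = FALSE)
}

test_that("the cohort report has the expected shape", {
  df <- make_feature_df(c("normal", "arterial_dysfunction",
                          "venous_dysfunction"),
                        c("anastomosis", "arterial_puncture",
                          "venous_puncture"), 8)
  rep <- build_report(df)
  gt <- rep$group_table
  expect_equal(nrow(gt), 3 * 4 * 3)   # sites x features x groups
  # two comparison columns per site/feature (non-reference groups)
  expect_equal(sum(!is.na(gt$p_value)), 3 * 4 * 2)
  expect_true(all(gt$summary != ""))
})

test_that("AVG reports mark the anastomosis rows N/A", {
  df <- make_feature_df(c("normal", "graft_dysfunction"),
                        c("arterial_puncture", "venous_puncture"), 6,
                        access = "AVG")
  rep <- build_report(df)
  ana <- rep$group_table[rep$group_table$site == "anastomosis", ]
  expect_gt(nrow(ana), 0)
  expect_true(all(ana$summary == "N/A"))
})

test_that("single-group input yields summaries without p-values", {
  df <- make_feature_df("normal", "arterial_puncture", 10)
  rep <- build_report(df)
  expect_true(all(is.na(rep$group_table$p_value)))
})

test_that("a missing reference group is an error", {
  df <- make_feature_df(c("arterial_dysfunction", "venous_dysfunction"),
                        "arterial_puncture", 6)
  expect_error(build_report(df), "report_reference_missing")
})

test_that("paired phases produce a pre/post table keyed by patient", {
  pre <- make_feature_df("venous_dysfunction", "arterial_puncture", 12,
                         seed = 10, phase = "pre_PTA")
  post <- pre
  post$phase <- "post_PTA"
  set.seed(11)
  post$mean_valley <- pre$mean_valley * exp(rnorm(12, log(2), 0.2))
  norm <- make_feature_df("normal", "arterial_puncture", 6, seed = 12)
  rep <- build_report(rbind(pre, post, norm))
  expect_false(is.null(rep$paired_table))
  pv <- rep$paired_table[rep$paired_table$feature == "mean_valley", ]
  expect_equal(pv$n_pairs, 12)
  expect_lt(pv$p_value, 0.05)
})
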