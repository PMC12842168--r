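cfg <- pipeline_config()

test_that("extrema of a raised-cosine contour sit at analytic positions", {
  fs <- 4000
  t <- (0:(10 * fs - 1)) / fs
  env <- (1 - cos(2 * pi * t)) / 2   # 1 Hz, valleys at integers
  ex <- detect_extrema(env, cfg)
  expect_length(ex$peak_indices, 10)
  expect_gte(length(ex$valley_indices), 9)
  analytic_peaks <- round((seq(0.5, 9.5, by = 1)) * fs) + 1
  expect_true(all(abs(ex$peak_indices - analytic_peaks) <= 5))
  analytic_valleys <- round(seq(1, 9) * fs) + 1
  expect_true(all(vapply(ex$valley_indices, function(i)
    min(abs(i - analytic_valleys)) <= 5, logical(1))))
})

test_that("a constant contour yields empty, flagged extrema", {
  ex <- detect_extrema(rep(0.3, 5000), cfg)
  expect_length(ex$peak_indices, 0)
  expect_length(ex$valley_indices, 0)
  expect_equal(ex$flag, "no_extrema")
})

test_that("of two close maxima only the taller survives the spacing rule", {
  fixed <- pipeline_config(adaptive_min_distance = FALSE)
  x <- rep(0, 3000)
  x[800 + -50:50] <- 1.0 * (1 - abs(-50:50) / 51)
  x[1400 + -50:50] <- 0.8 * (1 - abs(-50:50) / 51)   # 600 samples away
  ex <- detect_extrema(x, fixed)
  expect_equal(ex$peak_indices, 800)
  # moved beyond the 1000-sample floor, both survive
  y <- rep(0, 3000)
  y[800 + -50:50] <- 1.0 * (1 - abs(-50:50) / 51)
  y[1900 + -50:50] <- 0.8 * (1 - abs(-50:50) / 51)
  expect_equal(detect_extrema(y, fixed)$peak_indices, c(800, 1900))
})

test_that("retained extrema honor the spacing floor on rough signals", {
  fixed <- pipeline_config(adaptive_min_distance = FALSE)
  set.seed(99)
  for (i in 1:5) {
    x <- cumsum(rnorm(8000))
    ex <- detect_extrema(x, fixed)
    if (length(ex$peak_indices) > 1) {
      expect_true(all(diff(ex$peak_indices) >= 1000))
    }
    if (length(ex$valley_indices) > 1) {
      expect_true(all(diff(ex$valley_indices) >= 1000))
    }
  }
})

test_that("peak finding agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(5)
  # smooth signal with well-separated peaks
  t <- seq(0, 10, length.out = 5000)
  x <- sin(2 * pi * 0.8 * t) + 0.2 * sin(2 * pi * 2.7 * t)
  mine <- phonoaccess:::local_maxima(x)
  ref <- sort(pracma::findpeaks(x)[, 2])
  expect_equal(mine, ref)
})

test_that("IQR fence matches the hand-derived example and small-n policy", {
  x <- c(0.10, 0.44, 0.45, 0.46, 0.47, 0.95)
  # type-7 quartiles: Q1 = 0.4425, Q3 = 0.4675, IQR = 0.025
  # fence [0.44, 0.47] keeps the four central values
  expect_equal(x[reject_outliers(x, cfg)], c(0.44, 0.45, 0.46, 0.47))
  expect_true(all(reject_outliers(rep(0.4, 4), cfg)))         # IQR = 0
  expect_true(all(reject_outliers(c(10, -99, 0.2), cfg)))     # n < 4
  expect_length(reject_outliers(numeric(0), cfg), 0)
})

test_that("IQR fence equals the brute-force oracle on gridded sets", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    x <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)
    expect_identical(reject_outliers(x, cfg), brute_iqr_keep(x, 0.1))
  }
})

test_that("loudness features are means and their ratio, NA when undefined", {
  pv <- list(peak_amplitudes = c(0.4, 0.5), valley_amplitudes = c(0.1, 0.1))
  lf <- loudness_features(pv)
  expect_equal(lf$mean_peak, 0.45)
  expect_equal(lf$mean_valley, 0.1)
  expect_equal(lf$peak_valley_ratio, 4.5)

  empty <- list(peak_amplitudes = c(0.4), valley_amplitudes = numeric(0))
  expect_true(is.na(loudness_features(empty)$peak_valley_ratio))
  zero <- list(peak_amplitudes = c(0.4), valley_amplitudes = c(0, 0))
  expect_true(is.na(loudness_features(zero)$peak_valley_ratio))
})

test_that("band percentage splits pure tones and mixtures correctly", {
  pv <- list(valley_indices = 1L)
  expect_gt(low_frequency_pct(make_tone_filtered(100), pv, cfg), 99)
  expect_lt(low_frequency_pct(make_tone_filtered(300), pv, cfg), 1)
  fs <- 4000
  t <- (0:(10 * fs - 1)) / fs
  mix <- as_filtered(sin(2 * pi * 100 * t) + sin(2 * pi * 300 * t), fs)
  expect_equal(as.numeric(low_frequency_pct(mix, pv, cfg)), 50,
               tolerance = 2 / 50)
})

test_that("band areas partition: low plus high share is exactly 100", {
  set.seed(8)
  freq <- seq(0, 2000, by = 0.4)
  mag <- abs(rnorm(length(freq)))
  al <- phonoaccess:::band_auc(freq, mag, 20, 150)
  ah <- phonoaccess:::band_auc(freq, mag, 150, 500)
  expect_identical(100 * al / (al + ah) + 100 * ah / (al + ah), 100)
})

test_that("short tails after the first valley fall back and flag", {
  fs <- 4000
  x <- make_tone_filtered(100, fs = fs, dur = 10)
  # first valley so late that < 5 s but >= 2 s remains
  pv <- list(valley_indices = as.integer(7 * fs))
  out <- low_frequency_pct(x, pv, cfg)
  # non-integer cycle count in the 3 s tail leaks some area into the
  # high band, so the share drops below the full-segment value
  expect_gt(as.numeric(out), 90)
  expect_equal(attr(out, "flag"), "short_spectral_segment")
  # < 2 s remains: undefined
  pv2 <- list(valley_indices = as.integer(9.5 * fs))
  expect_true(is.na(low_frequency_pct(x, pv2, cfg)))
  # no valley at all
  expect_true(is.na(low_frequency_pct(x, list(valley_indices = integer(0)),
                                      cfg)))
})

test_that("feature extraction is deterministic and recovers the envelope ratio", {
  rec <- sim_recording(5, seed = 21)
  f1 <- extract_features(rec, cfg)
  f2 <- extract_features(rec, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_lt(abs(f1$peak_valley_ratio - 5) / 5, 0.2)
  expect_gt(f1$mean_peak, f1$mean_valley)
  expect_equal(f1$n_peaks + f1$n_rejected_peaks > 0, TRUE)
})

test_that("lower diastolic envelope never decreases the extracted ratio", {
  ratios <- c(3, 6, 12)   # peak fixed, valley scaled down
  got <- vapply(ratios, function(r) {
    extract_features(sim_recording(r, seed = 77), cfg)$peak_valley_ratio
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("site ratio profiles localize the largest downstream drop", {
  prof <- site_ratio_profile(
    c(anastomosis = 10.6, arterial_puncture = 8.5, venous_puncture = 5.9),
    cfg)
  expect_true(prof$conclusive)
  expect_equal(prof$boundary, c("arterial_puncture", "venous_puncture"))

  flat <- site_ratio_profile(
    c(anastomosis = 5.0, arterial_puncture = 5.0, venous_puncture = 5.0),
    cfg)
  expect_false(flat$conclusive)

  # an undefined site drops out; the remaining pair still resolves
  partial <- site_ratio_profile(
    c(anastomosis = 10.6, arterial_puncture = NA, venous_puncture = 5.0),
    cfg)
  expect_true(partial$conclusive)
  expect_equal(partial$boundary, c("anastomosis", "venous_puncture"))

  lone <- site_ratio_profile(c(anastomosis = 10.6, arterial_puncture = NA),
                             cfg)
  expect_false(lone$conclusive)
  expect_error(site_ratio_profile(c(5, 4, 3), cfg), "profile_unnamed")
})
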