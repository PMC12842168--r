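cfg <- pipeline_config()

test_that("identical seeds give identical recordings", {
  p <- simulation_params(seed = 31, noise_rms = 0.05)
  a <- generate_recording(p)
  b <- generate_recording(p)
  expect_identical(a$samples, b$samples)
  c <- generate_recording(simulation_params(seed = 32, noise_rms = 0.05))
  expect_false(identical(a$samples, c$samples))
})

test_that("the noise-free envelope hits its analytic extrema exactly", {
  p <- simulation_params(heart_rate = 60, peak_amp = 0.5, valley_amp = 0.1,
                         noise_rms = 0, jitter_pct = 0, amp_jitter = 0,
                         duration = 10, seed = 1)
  env <- bruit_envelope(p)
  fs <- p$sample_rate
  expect_equal(max(env), 0.5, tolerance = 1e-9)
  expect_equal(min(env), 0.1, tolerance = 1e-9)
  expect_equal(max(env) / min(env), 5, tolerance = 1e-9)
  # peaks at t = 0.5, 1.5, ... (valley-aligned cycles at 60 bpm)
  peak_idx <- which(env > 0.5 - 1e-9)
  expect_true(all(abs(((peak_idx - 1) / fs) %% 1 - 0.5) < 2 / fs))
})

test_that("generated samples stay within the 16-bit range", {
  for (s in 1:3) {
    rec <- generate_recording(simulation_params(seed = s, noise_rms = 0.1,
                                                amp_jitter = 0.5))
    expect_true(all(rec$samples >= -32768 & rec$samples <= 32767))
    expect_equal(max(abs(rec$samples)), round(0.9 * 32767))
  }
})

test_that("carrier spectral energy obeys low_band_fraction", {
  # all-low carrier: >= 99% of energy below 150 Hz
  comp <- phonoaccess:::sim_components(
    simulation_params(seed = 4, low_band_fraction = 1))
  fs <- 4000
  spec <- Mod(fft(comp$carrier))^2
  freq <- (seq_along(spec) - 1) * fs / length(spec)
  half <- freq <= fs / 2
  frac_low <- sum(spec[half & freq < 150]) / sum(spec[half])
  expect_gt(frac_low, 0.99)

  # extracted spectral-area share recovers the fraction within 5 points
  for (lbf in c(0.3, 0.6)) {
    p <- simulation_params(seed = 40 + round(100 * lbf), noise_rms = 0,
                           low_band_fraction = lbf)
    f <- extract_features(generate_recording(p), cfg)
    expect_lt(abs(f$low_frequency_pct - 100 * lbf), 5)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(simulation_params(valley_amp = 0.7, peak_amp = 0.6),
               "params_invalid")
  expect_error(simulation_params(heart_rate = 20), "params_invalid")
  expect_error(simulation_params(duration = 2), "params_invalid")
  expect_error(simulation_params(low_band_fraction = 1.2), "params_invalid")
})

test_that("cohorts have the right size, determinism and ground truth", {
  coh <- generate_cohort(c("normal_avf", "arterial_dysfunction",
                           "venous_dysfunction"), 5, seed = 9)
  expect_length(coh$recordings, 15)
  expect_equal(nrow(coh$manifest), 15)
  expect_true(all(c("gt_ratio", "gt_seed", "gt_low_band_fraction") %in%
                    names(coh$manifest)))
  coh2 <- generate_cohort(c("normal_avf", "arterial_dysfunction",
                            "venous_dysfunction"), 5, seed = 9)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$recordings[[1]]$samples,
                   coh2$recordings[[1]]$samples)
  expect_error(generate_cohort("no_such_scenario", 2, seed = 1),
               "scenario_unknown")
})

test_that("generated envelope ratios reproduce the clinical ordering", {
  coh <- generate_cohort(c("normal_avf", "venous_dysfunction"), 20,
                         seed = 15)
  m <- coh$manifest
  expect_gt(median(m$gt_ratio[m$group == "venous_dysfunction"]),
            median(m$gt_ratio[m$group == "normal"]))
})

test_that("paired post scenarios share patients and correlate draws", {
  coh <- generate_cohort(c("venous_dysfunction", "venous_dysfunction_post"),
                         10, seed = 22)
  m <- coh$manifest
  pre <- m[m$phase == "pre_PTA", ]
  post <- m[m$phase == "post_PTA", ]
  expect_setequal(pre$patient_id, post$patient_id)
  post <- post[match(pre$patient_id, post$patient_id), ]
  expect_gt(cor(log(pre$gt_ratio), log(post$gt_ratio)), 0.5)
  # post-angioplasty ratios move toward normal
  expect_lt(median(post$gt_ratio), median(pre$gt_ratio))
})

test_that("cohorts write WAVs and a manifest that extract_manifest can use", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort("normal_avf", 2, seed = 5, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.wav$"), 2)
  ft <- extract_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(ft), 2)
  expect_false(any(is.na(ft$peak_valley_ratio)))
  # WAV round trip reproduces the in-memory recording exactly
  wav <- read_wav(file.path(dir, coh$manifest$file[1]))
  expect_equal(wav$samples, as.integer(coh$recordings[[1]]$samples))
})
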