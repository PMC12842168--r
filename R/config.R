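#' Pipeline configuration
#'
#' Collects every tunable constant of the digitization pipeline in one
#' validated object. The defaults encode the standard analysis settings:
#' a 20--500 Hz analysis band, a 500-sample rolling-mean contour window,
#' a 1000-sample minimum spacing between detected peaks (or valleys), a
#' strict 0.1 x IQR outlier fence on peak/valley amplitudes, normalization
#' by the 99th percentile of the rectified signal (the 90th percentile of
#' the contour is retained as a QC scalar), a 5-second spectral segment,
#' and the 20--150 / 150--500 Hz low/high band split.
#'
#' Sample-count parameters (`contour_window`, `min_peak_distance`) are
#' interpreted relative to `assumed_sample_rate` (default 4000 Hz, so
#' 500 samples = 125 ms and 1000 samples = 250 ms) and are rescaled
#' proportionally when a recording's rate differs, keeping the
#' time-domain semantics invariant across sampling rates. 4000 Hz is the
#' smallest standard rate consistent with the acquisition device's stated
#' 20--1000 Hz bandwidth, and makes the smoothing window short relative
#' to a cardiac cycle while the spacing floor spans a systolic burst; the
#' package vignette documents the calibration behind this choice.
#'
#' With `adaptive_min_distance` (the default), `min_peak_distance` acts
#' as a floor: the effective spacing is raised to 60% of the cardiac
#' period estimated from the contour autocorrelation, so at most one peak
#' and one valley are retained per cardiac cycle. Setting it to `FALSE`
#' reverts to the fixed floor.
#'
#' @param band_low,band_high Analysis band edges in Hz.
#' @param contour_window Rolling-mean window, in samples at
#'   `assumed_sample_rate`.
#' @param min_peak_distance Minimum distance between retained peaks (and,
#'   separately, valleys), in samples at `assumed_sample_rate`.
#' @param iqr_multiplier Fence width multiplier `k` for the
#'   `[Q1 - k*IQR, Q3 + k*IQR]` amplitude outlier rule.
#' @param raw_percentile Percentile of the rectified signal used as the
#'   normalization denominator (0-100 scale).
#' @param contour_percentile Percentile of the contour retained as a QC
#'   scalar (0-100 scale).
#' @param spectral_segment Length in seconds of the spectral segment taken
#'   from the first detected valley.
#' @param low_band,high_band Two-element Hz intervals partitioning the
#'   analysis band into the low (cardiac rhythm) and mid-to-high
#'   (turbulence) bands; they must abut.
#' @param alpha Significance level used throughout the cohort statistics.
#' @param assumed_sample_rate Reference rate in Hz at which the
#'   sample-count parameters are expressed.
#' @param adaptive_min_distance Raise the peak/valley spacing to a
#'   fraction of the estimated cardiac period (default `TRUE`).
#' @param cycle_fraction Fraction of the estimated cardiac period used as
#'   the adaptive spacing.
#' @param profile_tolerance Relative drop below which a site ratio profile
#'   is called flat (see [site_ratio_profile()]).
#' @param min_duration,max_duration Validity window, in seconds, for
#'   recording durations.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$band_high
#' @export
pipeline_config <- function(band_low = 20,
                            band_high = 500,
                            contour_window = 500,
                            min_peak_distance = 1000,
                            iqr_multiplier = 0.1,
                            raw_percentile = 99,
                            contour_percentile = 90,
                            spectral_segment = 5,
                            low_band = c(20, 150),
                            high_band = c(150, 500),
                            alpha = 0.05,
                            assumed_sample_rate = 4000,
                            adaptive_min_distance = TRUE,
                            cycle_fraction = 0.6,
                            profile_tolerance = 0.2,
                            min_duration = 5,
                            max_duration = 30) {
  cfg <- list(
    band_low = band_low, band_high = band_high,
    contour_window = as.integer(contour_window),
    min_peak_distance = as.integer(min_peak_distance),
    iqr_multiplier = iqr_multiplier,
    raw_percentile = raw_percentile,
    contour_percentile = contour_percentile,
    spectral_segment = spectral_segment,
    low_band = as.numeric(low_band), high_band = as.numeric(high_band),
    alpha = alpha,
    assumed_sample_rate = assumed_sample_rate,
    adaptive_min_distance = isTRUE(adaptive_min_distance),
    cycle_fraction = cycle_fraction,
    profile_tolerance = profile_tolerance,
    min_duration = min_duration, max_duration = max_duration
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$band_low > 0, cfg$band_low < cfg$band_high,
    length(cfg$low_band) == 2, length(cfg$high_band) == 2,
    cfg$low_band[1] < cfg$low_band[2], cfg$high_band[1] < cfg$high_band[2]
  )
  if (cfg$low_band[1] < cfg$band_low || cfg$low_band[2] > cfg$band_high ||
      cfg$high_band[1] < cfg$band_low || cfg$high_band[2] > cfg$band_high) {
    stop("low_band and high_band must lie within [band_low, band_high]",
         call. = FALSE)
  }
  if (cfg$low_band[2] != cfg$high_band[1]) {
    stop("low_band and high_band must abut (share one edge)", call. = FALSE)
  }
  stopifnot(
    cfg$contour_window >= 1, cfg$min_peak_distance >= 1,
    cfg$iqr_multiplier >= 0,
    cfg$raw_percentile > 0, cfg$raw_percentile <= 100,
    cfg$contour_percentile > 0, cfg$contour_percentile <= 100,
    cfg$spectral_segment > 0,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$assumed_sample_rate > 0,
    cfg$cycle_fraction > 0, cfg$cycle_fraction <= 1,
    cfg$min_duration > 0, cfg$min_duration < cfg$max_duration
  )
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  band: %g-%g Hz (low %g-%g, high %g-%g)\n",
              x$band_low, x$band_high, x$low_band[1], x$low_band[2],
              x$high_band[1], x$high_band[2]))
  cat(sprintf("  contour window: %d samples @ %g Hz; min peak distance: %d\n",
              x$contour_window, x$assumed_sample_rate, x$min_peak_distance))
  cat(sprintf("  outlier fence: %g x IQR; normalization: P%g raw / P%g contour\n",
              x$iqr_multiplier, x$raw_percentile, x$contour_percentile))
  cat(sprintf("  spectral segment: %g s; alpha: %g\n",
              x$spectral_segment, x$alpha))
  invisible(x)
}

# Sample-count parameters are stated at the assumed reference rate; rescale
# to the actual rate so window/spacing durations are preserved.
effective_samples <- function(n_ref, sample_rate, config) {
  max(1L, as.integer(round(n_ref * sample_rate / config$assumed_sample_rate)))
}

# Fixed percentile definition for the whole package: linear interpolation
# between order statistics (type 7), on the 0-100 scale.
pct_quantile <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE, na.rm = FALSE)
}
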