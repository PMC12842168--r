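#' Bandpass filter a recording to the bruit analysis band
#'
#' Vascular-access bruits carry their useful energy at low frequencies
#' (turbulence mostly below ~500 Hz, with sub-20 Hz dominated by motion
#' and baseline artifact), so the first pipeline stage restricts each
#' recording to the 20-500 Hz band. A 4th-order Butterworth bandpass is
#' applied forward and backward (zero phase), giving an effective 8-pole
#' rolloff: the maximally flat passband preserves relative loudness and
#' the zero phase preserves peak timing.
#'
#' @param recording An [audio_recording()].
#' @param config A [pipeline_config()] supplying `band_low` / `band_high`.
#' @return A `filtered_signal`: list with `values`, `sample_rate`, `band`.
#' @export
bandpass <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate
  if (fs <= 2 * config$band_high) {
    stop(sprintf(
      "band_undefined: sample rate %g Hz must exceed twice band_high (%g Hz)",
      fs, config$band_high), call. = FALSE)
  }
  bf <- signal::butter(4, c(config$band_low, config$band_high) / (fs / 2),
                       type = "pass")
  values <- as.numeric(signal::filtfilt(bf, recording$samples))
  structure(
    list(values = values, sample_rate = fs,
         band = c(config$band_low, config$band_high)),
    class = "filtered_signal"
  )
}

#' Full-wave rectify a filtered signal
#'
#' Elementwise absolute value; makes all amplitudes non-negative so the
#' contour tracks loudness rather than signed pressure.
#'
#' @param signal A `filtered_signal` (from [bandpass()]) or numeric vector.
#' @return Same structure with non-negative `values` (numeric in, numeric
#'   out).
#' @export
rectify <- function(signal) {
  if (is.numeric(signal)) return(abs(signal))
  stopifnot(inherits(signal, "filtered_signal"))
  signal$values <- abs(signal$values)
  signal$rectified <- TRUE
  signal
}

# O(n) centered rolling mean with shrinking windows at the edges. For a
# window of w samples, position i averages indices
# [i - floor((w-1)/2), i + ceiling((w-1)/2)], clipped to the signal.
rolling_mean <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 1, n >= 1)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - hl, 1L)
  b <- pmin(i + hr, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Extract the generalized loudness contour
#'
#' Applies a centered rolling mean (500 samples at the 8 kHz reference
#' rate, i.e. 62.5 ms; rescaled proportionally for other rates) to the
#' rectified signal, suppressing carrier-frequency fluctuation and leaving
#' the systolic/diastolic loudness envelope. Edges use shrinking windows
#' (the mean over available samples) so output length equals input length
#' and extremum indices map directly to time.
#'
#' @param rectified A rectified `filtered_signal` or non-negative numeric
#'   vector.
#' @param config A [pipeline_config()].
#' @return Numeric vector, same length as the input.
#' @export
extract_contour <- function(rectified, config = pipeline_config()) {
  if (inherits(rectified, "filtered_signal")) {
    x <- rectified$values
    fs <- rectified$sample_rate
  } else {
    x <- as.numeric(rectified)
    fs <- config$assumed_sample_rate
  }
  w <- effective_samples(config$contour_window, fs, config)
  if (length(x) < w) {
    stop(sprintf(
      "signal_too_short: %d samples < contour window of %d",
      length(x), w), call. = FALSE)
  }
  rolling_mean(x, w)
}

#' Normalize the contour to relative loudness units
#'
#' Divides the contour by the 99th percentile of the rectified filtered
#' signal, making the result invariant to the recording's absolute gain
#' (multiplying the raw signal by any positive constant leaves the
#' normalized contour unchanged). The 90th percentile of the
#' pre-normalization contour is retained as a QC scalar
#' (`contour_p90`).
#'
#' @param contour Numeric contour from [extract_contour()].
#' @param rectified The rectified `filtered_signal` (or numeric vector)
#'   the contour was computed from.
#' @param config A [pipeline_config()].
#' @return A `contour_signal`: list with `values` (non-negative,
#'   dimensionless), `sample_rate`, `norm_denominator` and `contour_p90`.
#' @export
normalize_contour <- function(contour, rectified,
                              config = pipeline_config()) {
  if (inherits(rectified, "filtered_signal")) {
    rx <- rectified$values
    fs <- rectified$sample_rate
  } else {
    rx <- as.numeric(rectified)
    fs <- config$assumed_sample_rate
  }
  stopifnot(length(contour) == length(rx))
  denom <- pct_quantile(rx, config$raw_percentile)
  if (!is.finite(denom) || denom <= 0) {
    stop("silent_recording: normalization percentile of the rectified signal is zero",
         call. = FALSE)
  }
  structure(
    list(values = contour / denom, sample_rate = fs,
         norm_denominator = denom,
         contour_p90 = pct_quantile(contour, config$contour_percentile)),
    class = "contour_signal"
  )
}

#' @export
print.contour_signal <- function(x, ...) {
  cat(sprintf(
    "<contour_signal> %d samples @ %g Hz | norm denominator %.4g | contour P90 %.4g\n",
    length(x$values), x$sample_rate, x$norm_denominator, x$contour_p90))
  invisible(x)
}

# bandpass -> rectify -> contour -> normalize, returning the intermediates
# the feature stage needs.
preprocess_recording <- function(recording, config = pipeline_config()) {
  filtered <- bandpass(recording, config)
  rect <- rectify(filtered)
  contour <- extract_contour(rect, config)
  normalized <- normalize_contour(contour, rect, config)
  list(filtered = filtered, rectified = rect, contour = normalized)
}
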