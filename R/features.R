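# Normalized autocorrelation by FFT (O(n log n)), lags 0..n-1.
fft_autocorr <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[seq_len(n)]
  if (ac[1] <= 0) return(rep(0, n))
  ac / ac[1]
}

# Cardiac period estimate (in samples) from the loudness contour: the lag
# of the autocorrelation maximum over physiologic periods (heart rates
# 30-200 bpm). NA when the signal is too short or aperiodic (flat acf).
estimate_cycle_samples <- function(x, fs) {
  lag_min <- round(0.3 * fs)
  lag_max <- min(round(2 * fs), length(x) - 1)
  if (lag_max <= lag_min) return(NA_integer_)
  ac <- fft_autocorr(x)[-1]
  win <- ac[lag_min:lag_max]
  if (all(!is.finite(win)) || max(win) <= 0) return(NA_integer_)
  as.integer(which.max(win) + lag_min - 1)
}

# Candidate local maxima of x, with plateau handling: a flat run that is
# approached from below and left downward yields its middle sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- sign(diff(x))
  r <- rle(s)
  ends <- cumsum(r$lengths)          # diff-index where each run ends
  k <- length(r$values)
  out <- integer(0)
  for (j in seq_len(k - 1)) {
    if (r$values[j] != 1) next
    e <- ends[j]                     # last rising diff; x[e + 1] is the top
    if (r$values[j + 1] == -1) {
      out <- c(out, e + 1L)
    } else if (r$values[j + 1] == 0 && j + 2 <= k &&
               r$values[j + 2] == -1) {
      left <- e + 1L
      right <- ends[j + 1] + 1L      # plateau spans left..right
      out <- c(out, (left + right) %/% 2L)
    }
  }
  out
}

# Enforce a minimum index spacing, keeping the larger amplitude when two
# candidates conflict: candidates are visited in descending amplitude
# (ties: leftmost first) and each survivor invalidates all remaining
# candidates closer than min_dist.
enforce_min_distance <- function(idx, amp, min_dist) {
  m <- length(idx)
  if (m <= 1) return(rep(TRUE, m))
  keep <- rep(TRUE, m)
  for (j in order(-amp, idx)) {
    if (!keep[j]) next
    nb <- which(keep & abs(idx - idx[j]) < min_dist)
    nb <- nb[nb != j]
    keep[nb] <- FALSE
  }
  keep
}

#' Detect candidate peaks and valleys on the loudness contour
#'
#' Peaks are local maxima of the normalized contour; valleys are local
#' maxima of the negated contour (symmetric treatment). Each set
#' separately enforces a minimum spacing, keeping the larger-amplitude
#' candidate when two conflict, so stochastic wiggles of the smoothed
#' turbulence carrier are not counted as separate cardiac events. The
#' configured spacing (1000 samples at the 4 kHz reference rate, 250 ms)
#' is a floor; by default the effective spacing is raised to
#' `cycle_fraction` (60%) of the cardiac period estimated from the
#' contour autocorrelation, which retains at most one systolic peak and
#' one diastolic valley per cycle across the physiologic heart-rate
#' range.
#'
#' @param contour A `contour_signal` from [normalize_contour()] (or a
#'   numeric vector, taken to be at the reference rate).
#' @param config A [pipeline_config()].
#' @return A list with `peak_indices`, `peak_amplitudes`,
#'   `valley_indices`, `valley_amplitudes` and `flag` (`"no_extrema"` for
#'   a constant contour, otherwise `""`).
#' @export
detect_extrema <- function(contour, config = pipeline_config()) {
  if (inherits(contour, "contour_signal")) {
    x <- contour$values
    fs <- contour$sample_rate
  } else {
    x <- as.numeric(contour)
    fs <- config$assumed_sample_rate
  }
  min_dist <- effective_samples(config$min_peak_distance, fs, config)
  if (length(x) <= min_dist) {
    stop(sprintf("signal_too_short: %d samples <= min peak distance %d",
                 length(x), min_dist), call. = FALSE)
  }
  if (config$adaptive_min_distance) {
    cycle <- estimate_cycle_samples(x, fs)
    if (!is.na(cycle)) {
      min_dist <- max(min_dist, as.integer(round(config$cycle_fraction * cycle)))
    }
  }
  pk <- local_maxima(x)
  vl <- local_maxima(-x)
  pk <- pk[enforce_min_distance(pk, x[pk], min_dist)]
  vl <- vl[enforce_min_distance(vl, -x[vl], min_dist)]
  pk <- sort(pk)
  vl <- sort(vl)
  flag <- if (length(pk) == 0 && length(vl) == 0) "no_extrema" else ""
  list(peak_indices = pk, peak_amplitudes = x[pk],
       valley_indices = vl, valley_amplitudes = x[vl],
       flag = flag)
}

#' Reject amplitude outliers with a strict IQR fence
#'
#' Retains amplitudes within `[Q1 - k*IQR, Q3 + k*IQR]` (inclusive) of
#' their own candidate set, with `k = 0.1` by default -- far stricter than
#' the conventional 1.5, so that small non-physiological fluctuations are
#' aggressively suppressed and only amplitudes near the central
#' beat-to-beat level survive. Quartiles use linear interpolation between
#' order statistics. With fewer than 4 candidates the quartiles are not
#' meaningful and all values are retained.
#'
#' @param amplitudes Numeric candidate amplitudes.
#' @param config A [pipeline_config()] supplying `iqr_multiplier`.
#' @return Logical vector marking retained amplitudes.
#' @export
reject_outliers <- function(amplitudes, config = pipeline_config()) {
  n <- length(amplitudes)
  if (n == 0) return(logical(0))
  if (n < 4) return(rep(TRUE, n))
  q <- pct_quantile(amplitudes, c(25, 75))
  iqr <- q[2] - q[1]
  lo <- q[1] - config$iqr_multiplier * iqr
  hi <- q[2] + config$iqr_multiplier * iqr
  amplitudes >= lo & amplitudes <= hi
}

#' Peak/valley set after outlier rejection
#'
#' @param extrema Candidate extrema from [detect_extrema()].
#' @param config A [pipeline_config()].
#' @return An object of class `peak_valley_set` with retained indices and
#'   amplitudes and the counts removed by the IQR rule.
#' @export
peak_valley_set <- function(extrema, config = pipeline_config()) {
  keep_p <- reject_outliers(extrema$peak_amplitudes, config)
  keep_v <- reject_outliers(extrema$valley_amplitudes, config)
  structure(
    list(
      peak_indices = extrema$peak_indices[keep_p],
      peak_amplitudes = extrema$peak_amplitudes[keep_p],
      valley_indices = extrema$valley_indices[keep_v],
      valley_amplitudes = extrema$valley_amplitudes[keep_v],
      n_rejected_peaks = sum(!keep_p),
      n_rejected_valleys = sum(!keep_v),
      flag = extrema$flag
    ),
    class = "peak_valley_set"
  )
}

#' Loudness features from a peak/valley set
#'
#' Arithmetic means of the retained peak and valley amplitudes and their
#' ratio. The ratio is the acoustic analogue of pulsation over thrill: in
#' a healthy fistula the diastolic bruit (valley) stays comparatively
#' loud, while venous-outflow stenosis depresses the diastolic component
#' and inflates the ratio. Undefined quantities (no retained peaks or
#' valleys, or a zero mean valley) are `NA`, never 0.
#'
#' @param pv A `peak_valley_set`.
#' @return List with `mean_peak`, `mean_valley`, `peak_valley_ratio`.
#' @export
loudness_features <- function(pv) {
  mean_peak <- if (length(pv$peak_amplitudes) > 0) {
    mean(pv$peak_amplitudes)
  } else NA_real_
  mean_valley <- if (length(pv$valley_amplitudes) > 0) {
    mean(pv$valley_amplitudes)
  } else NA_real_
  ratio <- if (!is.na(mean_peak) && !is.na(mean_valley) && mean_valley > 0) {
    mean_peak / mean_valley
  } else NA_real_
  list(mean_peak = mean_peak, mean_valley = mean_valley,
       peak_valley_ratio = ratio)
}

# Trapezoidal area under (freq, mag) restricted to [lo, hi], with linear
# interpolation at the exact band edges.
band_auc <- function(freq, mag, lo, hi) {
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  m <- c(stats::approx(freq, mag, xout = lo)$y,
         mag[inside],
         stats::approx(freq, mag, xout = hi)$y)
  sum(diff(f) * (m[-length(m)] + m[-1]) / 2)
}

#' Low-frequency spectral component (%)
#'
#' Starting at the first detected valley, a 5-second segment of the
#' band-limited signal is taken and its single-taper magnitude spectrum
#' (periodogram) computed. The areas under the spectrum over the low band
#' (20-150 Hz, the fundamental cardiac rhythm) and the mid-to-high band
#' (150-500 Hz, turbulence) are integrated trapezoidally, and the
#' low-frequency component is `100 * AUC_low / (AUC_low + AUC_high)`.
#' Because the signal is already restricted to 20-500 Hz, the two bands
#' partition the analyzed energy.
#'
#' If fewer than 5 s remain after the first valley, the longest available
#' tail of at least 2 s is used and the result flagged
#' (`"short_spectral_segment"`); shorter still, the value is `NA`
#' (`"no_spectral_segment"`). Without any detected valley the value is
#' `NA` (`"no_valley"`).
#'
#' @param filtered A `filtered_signal` from [bandpass()].
#' @param pv A `peak_valley_set` (or any list with `valley_indices`).
#' @param config A [pipeline_config()].
#' @return A single percentage in \[0, 100\] (or `NA`), with attribute
#'   `"flag"`.
#' @export
low_frequency_pct <- function(filtered, pv, config = pipeline_config()) {
  stopifnot(inherits(filtered, "filtered_signal"))
  fs <- filtered$sample_rate
  x <- filtered$values
  if (length(pv$valley_indices) == 0) {
    return(structure(NA_real_, flag = "no_valley"))
  }
  start <- pv$valley_indices[1]
  avail <- length(x) - start + 1
  want <- round(config$spectral_segment * fs)
  flag <- ""
  if (avail >= want) {
    seg <- x[start:(start + want - 1)]
  } else if (avail >= round(2 * fs)) {
    seg <- x[start:length(x)]
    flag <- "short_spectral_segment"
  } else {
    return(structure(NA_real_, flag = "no_spectral_segment"))
  }
  nseg <- length(seg)
  spec <- Mod(stats::fft(seg))[seq_len(nseg %/% 2 + 1)]
  freq <- (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg
  auc_low <- band_auc(freq, spec, config$low_band[1], config$low_band[2])
  auc_high <- band_auc(freq, spec, config$high_band[1], config$high_band[2])
  total <- auc_low + auc_high
  if (!is.finite(total) || total <= 0) {
    return(structure(NA_real_, flag = "empty_spectrum"))
  }
  structure(100 * auc_low / total, flag = flag)
}

#' Extract the per-recording acoustic feature set
#'
#' Deterministic composition of the full pipeline: bandpass, rectify,
#' rolling-mean contour, percentile normalization, peak/valley detection
#' with IQR outlier rejection, loudness features, and the low-frequency
#' band percentage. QC flags from all stages are propagated.
#'
#' @param recording An [audio_recording()].
#' @param config A [pipeline_config()].
#' @return An object of class `acoustic_features`: `mean_peak`,
#'   `mean_valley`, `peak_valley_ratio`, `low_frequency_pct`, counts of
#'   retained and rejected extrema, QC `flags`, and the recording's
#'   `metadata`.
#' @examples
#' params <- simulation_params(seed = 1)
#' rec <- generate_recording(params)
#' extract_features(rec)
#' @export
extract_features <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "audio_recording"))
  pre <- preprocess_recording(recording, config)
  extrema <- detect_extrema(pre$contour, config)
  pv <- peak_valley_set(extrema, config)
  loud <- loudness_features(pv)
  lf <- low_frequency_pct(pre$filtered, pv, config)

  flags <- character(0)
  if (nzchar(pv$flag)) flags <- c(flags, pv$flag)
  if (nzchar(attr(lf, "flag"))) flags <- c(flags, attr(lf, "flag"))
  if (is.na(loud$peak_valley_ratio)) flags <- c(flags, "undefined_ratio")

  structure(
    list(
      mean_peak = loud$mean_peak,
      mean_valley = loud$mean_valley,
      peak_valley_ratio = loud$peak_valley_ratio,
      low_frequency_pct = as.numeric(lf),
      n_peaks = length(pv$peak_amplitudes),
      n_valleys = length(pv$valley_amplitudes),
      n_rejected_peaks = pv$n_rejected_peaks,
      n_rejected_valleys = pv$n_rejected_valleys,
      flags = paste(flags, collapse = ";"),
      metadata = recording$metadata
    ),
    class = "acoustic_features"
  )
}

#' @export
print.acoustic_features <- function(x, ...) {
  cat(sprintf(
    "<acoustic_features> peak %.3f | valley %.3f | ratio %.2f | low-freq %.1f%% (%d peaks, %d valleys)\n",
    x$mean_peak, x$mean_valley, x$peak_valley_ratio, x$low_frequency_pct,
    x$n_peaks, x$n_valleys))
  if (nzchar(x$flags)) cat("  flags:", x$flags, "\n")
  invisible(x)
}

#' @export
as.data.frame.acoustic_features <- function(x, ...) {
  data.frame(
    mean_peak = x$mean_peak, mean_valley = x$mean_valley,
    peak_valley_ratio = x$peak_valley_ratio,
    low_frequency_pct = x$low_frequency_pct,
    n_peaks = x$n_peaks, n_valleys = x$n_valleys,
    n_rejected_peaks = x$n_rejected_peaks,
    n_rejected_valleys = x$n_rejected_valleys,
    flags = x$flags, stringsAsFactors = FALSE
  )
}

#' Infer the stenosis side from a site-ordered ratio profile
#'
#' Along the access (anastomosis, then arterial puncture, then venous
#' puncture), the peak-to-valley ratio is expected to be elevated upstream
#' of a stenosis and lower downstream of it, so the boundary with the
#' largest relative ratio drop points at the stenotic segment. Profiles
#' that are flat within `config$profile_tolerance` (default 20% relative)
#' are reported as inconclusive rather than over-read.
#'
#' @param ratios Named numeric vector of peak-to-valley ratios in access
#'   order, e.g. `c(anastomosis = 10.6, arterial_puncture = 8.5,
#'   venous_puncture = 5.9)`. `NA` entries are dropped.
#' @param config A [pipeline_config()].
#' @return An object of class `ratio_profile`: the cleaned `profile`, the
#'   inferred `boundary` (two site names, or `NULL`), the `drop` fraction
#'   there, and `conclusive`.
#' @export
site_ratio_profile <- function(ratios, config = pipeline_config()) {
  stopifnot(is.numeric(ratios))
  if (is.null(names(ratios)) || any(!nzchar(names(ratios)))) {
    stop("profile_unnamed: ratios must be named by site, in access order",
         call. = FALSE)
  }
  profile <- ratios[!is.na(ratios)]
  if (length(profile) < 2) {
    return(structure(list(profile = profile, boundary = NULL,
                          drop = NA_real_, conclusive = FALSE),
                     class = "ratio_profile"))
  }
  drops <- -diff(profile) / profile[-length(profile)]
  best <- which.max(drops)
  conclusive <- drops[best] >= config$profile_tolerance
  structure(
    list(
      profile = profile,
      boundary = if (conclusive) names(profile)[c(best, best + 1)] else NULL,
      drop = if (conclusive) unname(drops[best]) else NA_real_,
      conclusive = conclusive
    ),
    class = "ratio_profile"
  )
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat("<ratio_profile>", paste(sprintf("%s=%.2f", names(x$profile),
                                       x$profile), collapse = " -> "), "\n")
  if (x$conclusive) {
    cat(sprintf("  largest ratio drop (%.0f%%) between %s and %s: stenosis inferred toward %s\n",
                100 * x$drop, x$boundary[1], x$boundary[2], x$boundary[2]))
  } else {
    cat("  profile flat within tolerance: inconclusive\n")
  }
  invisible(x)
}
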