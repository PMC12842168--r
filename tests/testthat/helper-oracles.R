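# Independent brute-force oracles. These deliberately avoid the package's
# cumulative-sum and quantile code paths.

# Literal centered rolling mean with shrinking edge windows.
brute_rolling_mean <- function(x, w) {
  n <- length(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - hl):min(n, i + hr)])
  }, numeric(1))
}

# Quartile by hand: linear interpolation between order statistics.
brute_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Literal IQR fence filter.
brute_iqr_keep <- function(x, k) {
  if (length(x) < 4) return(rep(TRUE, length(x)))
  q1 <- brute_quartile(x, 0.25)
  q3 <- brute_quartile(x, 0.75)
  x >= q1 - k * (q3 - q1) & x <= q3 + k * (q3 - q1)
}

# A filtered_signal wrapper around a plain waveform, for spectral tests.
as_filtered <- function(values, fs, band = c(20, 500)) {
  structure(list(values = values, sample_rate = fs, band = band),
            class = "filtered_signal")
}

make_tone_filtered <- function(freq, fs = 4000, dur = 10, amp = 1) {
  t <- (0:(dur * fs - 1)) / fs
  as_filtered(amp * sin(2 * pi * freq * t), fs)
}

sim_recording <- function(ratio, seed, noise_rms = 0.05, jitter = 0.02,
                          ...) {
  generate_recording(simulation_params(
    seed = seed, peak_amp = 0.6, valley_amp = 0.6 / ratio,
    noise_rms = noise_rms, jitter_pct = jitter, ...))
}

default_md <- function(...) {
  recording_metadata("T01", "AVF", "arterial_puncture", "normal", ...)
}
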