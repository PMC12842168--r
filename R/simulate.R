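# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parameters of a synthetic bruit
#'
#' Generative parameters for one simulated vascular-access recording. The
#' signal model is `envelope(t) * carrier(t) + noise(t)`:
#' a cardiac-cycle-periodic envelope swinging between `valley_amp`
#' (diastole) and `peak_amp` (systole), a unit-RMS band-limited noise
#' carrier whose magnitude-spectrum area is split between the 20-150 Hz
#' and 150-500 Hz bands in proportion `low_band_fraction :
#' 1 - low_band_fraction`, and additive white noise with RMS `noise_rms *
#' peak_amp`.
#'
#' `jitter_pct` is the cycle-to-cycle relative SD of the period;
#' `amp_jitter` the cycle-to-cycle coefficient of variation of a
#' whole-cycle loudness multiplier (log-normal, mean 1), which scales peak
#' and valley together and so models beat-to-beat loudness variability
#' without changing the envelope ratio. When `amp_jitter` is `NULL` it
#' defaults to `jitter_pct`.
#'
#' @param heart_rate Beats per minute, in \[30, 180\].
#' @param peak_amp Envelope maximum, in (0, 1\].
#' @param valley_amp Envelope minimum, in \[0, `peak_amp`).
#' @param envelope_shape `"raised_cosine"` (symmetric) or `"asymmetric"`
#'   (systolic pulse occupying `systole_fraction` of the cycle above a
#'   diastolic floor).
#' @param systole_fraction Fraction of the cycle occupied by the systolic
#'   pulse for the asymmetric shape.
#' @param low_band_fraction Fraction of carrier magnitude-spectrum area in
#'   the 20-150 Hz band, in \[0, 1\].
#' @param noise_rms Additive white-noise RMS relative to `peak_amp`.
#' @param duration Seconds, in \[5, 30\].
#' @param sample_rate Hz.
#' @param seed Integer seed; identical parameters and seed give identical
#'   recordings.
#' @param jitter_pct Relative SD of the cycle period.
#' @param amp_jitter Cycle amplitude coefficient of variation, or `NULL`.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(heart_rate = 70,
                              peak_amp = 0.6,
                              valley_amp = 0.12,
                              envelope_shape = c("raised_cosine", "asymmetric"),
                              systole_fraction = 1 / 3,
                              low_band_fraction = 0.4,
                              noise_rms = 0.02,
                              duration = 10,
                              sample_rate = 4000,
                              seed = 1L,
                              jitter_pct = 0.02,
                              amp_jitter = NULL) {
  envelope_shape <- match.arg(envelope_shape)
  p <- list(heart_rate = heart_rate, peak_amp = peak_amp,
            valley_amp = valley_amp, envelope_shape = envelope_shape,
            systole_fraction = systole_fraction,
            low_band_fraction = low_band_fraction, noise_rms = noise_rms,
            duration = duration, sample_rate = sample_rate,
            seed = as.integer(seed), jitter_pct = jitter_pct,
            amp_jitter = if (is.null(amp_jitter)) jitter_pct else amp_jitter)
  class(p) <- "simulation_params"
  validate_simulation_params(p)
}

validate_simulation_params <- function(p) {
  if (p$heart_rate < 30 || p$heart_rate > 180) {
    stop("params_invalid: heart_rate outside [30, 180] bpm", call. = FALSE)
  }
  if (p$peak_amp <= 0 || p$peak_amp > 1) {
    stop("params_invalid: peak_amp must be in (0, 1]", call. = FALSE)
  }
  if (p$valley_amp < 0 || p$valley_amp >= p$peak_amp) {
    stop("params_invalid: valley_amp must be in [0, peak_amp)", call. = FALSE)
  }
  if (p$duration < 5 || p$duration > 30) {
    stop("params_invalid: duration outside [5, 30] s", call. = FALSE)
  }
  if (p$low_band_fraction < 0 || p$low_band_fraction > 1) {
    stop("params_invalid: low_band_fraction outside [0, 1]", call. = FALSE)
  }
  if (p$noise_rms < 0 || p$jitter_pct < 0 || p$amp_jitter < 0) {
    stop("params_invalid: noise_rms and jitters must be non-negative",
         call. = FALSE)
  }
  if (p$envelope_shape == "asymmetric" &&
      (p$systole_fraction <= 0 || p$systole_fraction >= 1)) {
    stop("params_invalid: systole_fraction must be in (0, 1)", call. = FALSE)
  }
  p
}

# Deterministic components of one simulated recording. RNG draw order is
# fixed (cycle periods, cycle amplitudes, carrier spectrum, noise) so that
# the envelope alone can be re-derived under the same seed.
sim_components <- function(params) {
  with_local_seed(params$seed, {
    fs <- params$sample_rate
    n <- round(params$duration * fs)
    base_period <- 60 / params$heart_rate

    n_cycles <- ceiling(params$duration / base_period) + 5L
    periods <- base_period *
      pmax(0.4, 1 + stats::rnorm(n_cycles, 0, params$jitter_pct))
    sdlog <- sqrt(log1p(params$amp_jitter^2))
    amps <- stats::rlnorm(n_cycles, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    starts <- cumsum(c(0, periods))
    t <- (seq_len(n) - 1) / fs
    k <- findInterval(t, starts)
    phase <- (t - starts[k]) / periods[k]
    p <- params$peak_amp
    v <- params$valley_amp
    shape <- if (params$envelope_shape == "raised_cosine") {
      (1 - cos(2 * pi * phase)) / 2
    } else {
      ifelse(phase < params$systole_fraction,
             (1 - cos(2 * pi * phase / params$systole_fraction)) / 2, 0)
    }
    envelope <- amps[k] * (v + (p - v) * shape)

    carrier <- band_noise_carrier(n, fs, params$low_band_fraction)
    noise <- if (params$noise_rms > 0) {
      stats::rnorm(n, sd = params$noise_rms * p)
    } else {
      numeric(n)
    }
    list(t = t, envelope = envelope, carrier = carrier, noise = noise,
         cycle_starts = starts, cycle_periods = periods, cycle_amps = amps)
  })
}

# Unit-RMS noise carrier synthesized in the frequency domain: independent
# complex-Gaussian bins weighted so the expected magnitude-spectrum area
# over 20-150 Hz is `lbf` of the total over 20-500 Hz (per-Hz magnitude
# density lbf/130 in the low band, (1-lbf)/350 in the high band).
band_noise_carrier <- function(n, fs, lbf) {
  freq <- (seq_len(n) - 1) * fs / n
  half <- 2:(ceiling(n / 2))   # positive-frequency bins, excluding DC
  g <- numeric(n)
  f <- freq[half]
  g[half] <- ifelse(f >= 20 & f <= 150, lbf / 130,
                    ifelse(f > 150 & f <= 500, (1 - lbf) / 350, 0))
  spec <- complex(length.out = n)
  nb <- sum(g[half] > 0)
  if (nb == 0) stop("params_invalid: empty carrier spectrum", call. = FALSE)
  z <- complex(real = stats::rnorm(length(half)),
               imaginary = stats::rnorm(length(half)))
  spec[half] <- g[half] * z
  spec[n + 2 - half] <- Conj(spec[half])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate one synthetic bruit recording
#'
#' Builds `envelope(t) * carrier(t) + noise(t)` from a
#' [simulation_params()] object, scales the result to 90% of full scale,
#' and quantizes to 16-bit integers (round half to even). Identical
#' parameters and seed give bit-identical recordings.
#'
#' @param params A [simulation_params()].
#' @param metadata Optional [recording_metadata()]; defaults to a synthetic
#'   normal-AVF arterial-puncture recording labeled by the seed.
#' @param config A [pipeline_config()] (duration validity window).
#' @return An [audio_recording()] with the generating `params` attached as
#'   attribute `"params"`.
#' @examples
#' rec <- generate_recording(simulation_params(seed = 42))
#' rec
#' @export
generate_recording <- function(params, metadata = NULL,
                               config = pipeline_config()) {
  stopifnot(inherits(params, "simulation_params"))
  comp <- sim_components(params)
  x <- comp$envelope * comp$carrier + comp$noise
  peak <- max(abs(x))
  if (peak <= 0) stop("params_invalid: silent simulation", call. = FALSE)
  samples <- round(x / peak * (0.9 * 32767))
  if (is.null(metadata)) {
    metadata <- recording_metadata(
      patient_id = sprintf("SIM_%d", params$seed),
      access_type = "AVF", site = "arterial_puncture", group = "normal")
  }
  rec <- audio_recording(samples, params$sample_rate, metadata, config)
  attr(rec, "params") <- params
  rec
}

#' Envelope ground truth of a simulated recording
#'
#' Re-derives, under the recording's seed, the exact loudness envelope
#' used by [generate_recording()], for use as ground truth in recovery
#' tests.
#'
#' @param params A [simulation_params()].
#' @return Numeric envelope vector, one value per sample.
#' @export
bruit_envelope <- function(params) {
  sim_components(params)$envelope
}
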