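#' Audio recording of a vascular-access bruit
#'
#' Container for a digitized bruit: integer relative-loudness samples in
#' the 16-bit convention (-32768..32767), the sampling rate, and the
#' acquisition metadata. Recordings outside the configured duration
#' validity window (default 5-30 s; clinical acquisitions run 10-20 s)
#' are rejected.
#'
#' @param samples Numeric vector of integer sample values in -32768..32767.
#' @param sample_rate Sampling rate in Hz.
#' @param metadata A [recording_metadata()] object.
#' @param config A [pipeline_config()]; supplies the duration validity
#'   window.
#' @return An object of class `audio_recording` with fields `samples`,
#'   `sample_rate`, `duration` and `metadata`.
#' @export
audio_recording <- function(samples, sample_rate, metadata,
                            config = pipeline_config()) {
  stopifnot(inherits(metadata, "recording_metadata"))
  samples <- as.numeric(samples)
  if (length(samples) == 0) {
    stop("recording_empty: no samples", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("recording_invalid: non-finite samples", call. = FALSE)
  }
  if (any(samples < -32768 | samples > 32767)) {
    stop("recording_invalid: samples outside [-32768, 32767]", call. = FALSE)
  }
  duration <- length(samples) / sample_rate
  if (duration < config$min_duration || duration > config$max_duration) {
    stop(sprintf(
      "recording_duration: %.2f s outside validity window [%g, %g] s",
      duration, config$min_duration, config$max_duration), call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate,
         duration = duration, metadata = metadata),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.2f s) | %s %s %s\n",
              length(x$samples), x$sample_rate, x$duration,
              x$metadata$patient_id, x$metadata$access_type,
              x$metadata$site))
  invisible(x)
}

#' Read a bruit recording from a WAV file
#'
#' Reads a mono WAV file (any supported encoding; see [read_wav()]),
#' rescales samples to the 16-bit integer convention, and attaches the
#' supplied acquisition metadata unchanged.
#'
#' @inheritParams audio_recording
#' @param path Path to a mono WAV file.
#' @return An [audio_recording()].
#' @examples
#' \dontrun{
#' md <- recording_metadata("P01", "AVF", "arterial_puncture", "normal")
#' rec <- read_recording("p01_arterial.wav", md)
#' }
#' @export
read_recording <- function(path, metadata, config = pipeline_config()) {
  wav <- read_wav(path)
  audio_recording(wav$samples, wav$sample_rate, metadata, config)
}
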