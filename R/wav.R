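# Minimal RIFF/WAVE reader and writer for mono recordings.
#
# Supports PCM (format tag 1) at 8, 16, 24 and 32 bits and IEEE float
# (format tag 3) at 32 and 64 bits, including WAVE_FORMAT_EXTENSIBLE
# (format tag 0xFFFE) wrappers around either. All sample encodings are
# rescaled on read to the 16-bit signed integer convention
# (-32768..32767) used throughout the analysis.

#' Read a mono WAV file
#'
#' Parses a RIFF/WAVE file and returns the sample sequence rescaled to the
#' 16-bit signed integer convention (-32768..32767), whatever the on-disk
#' encoding: 8-bit unsigned PCM is shifted and scaled up, 24/32-bit PCM is
#' scaled down (round half to even), and float samples in \[-1, 1\] are
#' multiplied by 32767 and rounded.
#'
#' @param path Path to a mono WAV file.
#' @return A list with `samples` (numeric vector of integers in
#'   -32768..32767), `sample_rate` (Hz), `bits` and `encoding`
#'   (`"pcm"` or `"float"`).
#' @seealso [write_wav()], [read_recording()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("wav_unreadable: file not found: %s", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("wav_unreadable: not a RIFF file: %s", path), call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop(sprintf("wav_unreadable: not a WAVE file: %s", path), call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    chunk_id <- readChar(con, 4, useBytes = TRUE)
    if (length(chunk_id) == 0 || nchar(chunk_id) < 4) break
    chunk_size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(chunk_id, "fmt ")) {
      body <- readBin(con, "raw", chunk_size)
      fmt <- parse_fmt_chunk(body)
    } else if (identical(chunk_id, "data")) {
      data_raw <- readBin(con, "raw", chunk_size)
    } else {
      invisible(readBin(con, "raw", chunk_size))
    }
    if (chunk_size %% 2 == 1) invisible(readBin(con, "raw", 1))  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) {
    stop("wav_unreadable: missing fmt chunk", call. = FALSE)
  }
  if (is.null(data_raw) || length(data_raw) == 0) {
    stop("wav_empty: no audio data in file", call. = FALSE)
  }
  if (fmt$channels != 1) {
    stop(sprintf("wav_multichannel: expected mono, found %d channels",
                 fmt$channels), call. = FALSE)
  }

  samples <- decode_samples(data_raw, fmt)
  list(samples = samples, sample_rate = fmt$sample_rate,
       bits = fmt$bits, encoding = fmt$encoding)
}

parse_fmt_chunk <- function(body) {
  u16 <- function(off) {
    sum(as.integer(body[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.numeric(body[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  tag <- u16(0)
  channels <- u16(2)
  sample_rate <- u32(4)
  bits <- u16(14)
  if (tag == 0xFFFE && length(body) >= 26) {
    tag <- u16(24)  # first two bytes of the extensible sub-format GUID
  }
  encoding <- switch(as.character(tag),
    "1" = "pcm",
    "3" = "float",
    stop(sprintf("wav_unreadable: unsupported format tag %d", tag),
         call. = FALSE)
  )
  list(encoding = encoding, channels = channels,
       sample_rate = sample_rate, bits = bits)
}

decode_samples <- function(raw, fmt) {
  if (fmt$encoding == "float") {
    size <- fmt$bits / 8
    if (!size %in% c(4, 8)) {
      stop(sprintf("wav_unreadable: unsupported float width %d", fmt$bits),
           call. = FALSE)
    }
    x <- readBin(raw, "numeric", n = length(raw) / size, size = size,
                 endian = "little")
    return(round(x * 32767))
  }
  switch(as.character(fmt$bits),
    "8" = {
      x <- as.integer(readBin(raw, "integer", n = length(raw), size = 1,
                              signed = FALSE))
      (x - 128L) * 256L
    },
    "16" = readBin(raw, "integer", n = length(raw) / 2, size = 2,
                   signed = TRUE, endian = "little"),
    "24" = {
      n <- length(raw) %/% 3
      b <- matrix(as.integer(raw[seq_len(n * 3)]), nrow = 3)
      x <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
      x <- ifelse(x >= 8388608, x - 16777216, x)
      round(x / 256)
    },
    "32" = {
      x <- readBin(raw, "integer", n = length(raw) / 4, size = 4,
                   endian = "little")
      round(x / 65536)
    },
    stop(sprintf("wav_unreadable: unsupported PCM width %d", fmt$bits),
         call. = FALSE)
  )
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector of integer sample values in -32768..32767.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, sample_rate, path) {
  samples <- as.integer(round(samples))
  if (any(samples < -32768L | samples > 32767L)) {
    stop("wav_range: samples outside the 16-bit range", call. = FALSE)
  }
  n <- length(samples)
  data_bytes <- n * 2L
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop(sprintf(
                    "wav_unwritable: cannot open %s", path), call. = FALSE))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}
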