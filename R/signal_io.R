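#' Lung sound signal container
#'
#' A `lung_sound` carries a uniformly sampled, amplitude-normalized
#' auscultation signal through the whole pipeline: enhancement, respiratory
#' cycle segmentation, feature extraction and classification.
#'
#' @param samples Numeric vector of finite samples, nominally in `[-1, 1]`.
#' @param sampling_rate_hz Positive sampling rate in Hz. Clinical chest
#'   recordings in this package's target format are sampled at 8 kHz, the
#'   default used throughout.
#' @param label Optional class tag, one of `"normal"`, `"abnormal"` or
#'   `"unknown"`.
#' @return An object of class `lung_sound`: a list with elements `samples`,
#'   `sampling_rate_hz` and `label`.
#' @examples
#' s <- lung_sound(sin(2 * pi * 100 * seq(0, 1, by = 1 / 8000)))
#' s
#' @export
lung_sound <- function(samples, sampling_rate_hz = 8000,
                       label = c("unknown", "normal", "abnormal")) {
  stop_if_not_finite(samples, "samples")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number", call. = FALSE)
  }
  label <- match.arg(label)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 label = label),
            class = "lung_sound")
}

#' @export
print.lung_sound <- function(x, ...) {
  cat(sprintf("<lung_sound> %d samples @ %g Hz (%.3f s), label: %s\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$label))
  invisible(x)
}

#' @export
length.lung_sound <- function(x) length(x$samples)

# Coerce numeric vectors / lung_sound to bare samples.
as_samples <- function(x) {
  if (inherits(x, "lung_sound")) x$samples else as.numeric(x)
}

#' Read a lung-sound recording from a WAV file
#'
#' Reads single-channel 16-bit integer PCM RIFF/WAVE files, the storage
#' format used for the clinical recordings this pipeline targets. Samples
#' are scaled to `[-1, 1]` by dividing by 32768; the sampling rate is taken
#' from the file header.
#'
#' @param path Path to a mono, 16-bit PCM WAV file.
#' @param label Optional class tag attached to the returned signal.
#' @return A [lung_sound()] object.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, label = "unknown") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  read_u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  read_u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                                 endian = "little")

  riff <- readChar(con, 4L, useBytes = TRUE)
  read_u32() # RIFF chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop(sprintf("not a RIFF/WAVE file: %s", path), call. = FALSE)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- read_u32()
    if (identical(id, "fmt ")) {
      audio_format <- read_u16()
      n_channels <- read_u16()
      rate <- read_u32()
      read_u32() # byte rate
      read_u16() # block align
      bits <- read_u16()
      if (size > 16L) readBin(con, "raw", size - 16L)
      fmt <- list(audio_format = audio_format, n_channels = n_channels,
                  rate = rate, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk", call. = FALSE)
      if (fmt$audio_format != 1L) {
        stop(sprintf("unsupported WAV encoding (format tag %d); only integer PCM is supported",
                     fmt$audio_format), call. = FALSE)
      }
      if (fmt$n_channels != 1L) {
        stop(sprintf("only mono recordings are supported; file has %d channels",
                     fmt$n_channels), call. = FALSE)
      }
      if (fmt$bits != 16L) {
        stop(sprintf("only 16-bit PCM is supported; file is %d-bit", fmt$bits),
             call. = FALSE)
      }
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2L) # skip unknown chunk (word aligned)
    }
  }
  if (is.null(samples)) stop(sprintf("no data chunk found in %s", path), call. = FALSE)
  lung_sound(samples / 32768, fmt$rate, label)
}

#' Write a lung-sound signal to a 16-bit PCM mono WAV file
#'
#' Amplitudes are scaled by 32768, rounded half away from zero and clamped
#' to the 16-bit range, so a full-scale 1.0 sample is stored as 32767, zero
#' stays exactly zero, and a read-write round trip of any PCM file is
#' bit-identical.
#'
#' @param signal A [lung_sound()] object (or numeric vector, with
#'   `sampling_rate_hz` then required through a `lung_sound`).
#' @param path Output file path.
#' @param clip If `FALSE` (default), amplitudes outside `[-1, 1]` are an
#'   error naming the worst offending sample; if `TRUE` they are clipped.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(signal, path, clip = FALSE) {
  if (!inherits(signal, "lung_sound")) {
    stop("signal must be a lung_sound object", call. = FALSE)
  }
  x <- signal$samples
  over <- abs(x) > 1
  if (any(over)) {
    if (!clip) {
      worst <- which.max(abs(x))
      stop(sprintf(
        "amplitude out of range: |sample %d| = %.6f > 1 (set clip = TRUE to clip)",
        worst - 1L, abs(x[worst])), call. = FALSE)
    }
    x <- pmin(1, pmax(-1, x))
  }
  # round half away from zero; top-code 32768 -> 32767 so 1.0 is representable
  pcm <- as.integer(pmin(sign(x) * floor(abs(x) * 32768 + 0.5), 32767))

  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  data_bytes <- 2L * length(pcm)
  rate <- as.integer(round(signal$sampling_rate_hz))

  writeChar("RIFF", con, eos = NULL)
  w_u32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_u32(16L)
  w_u16(1L)            # PCM
  w_u16(1L)            # mono
  w_u32(rate)
  w_u32(rate * 2L)     # byte rate
  w_u16(2L)            # block align
  w_u16(16L)           # bits per sample
  writeChar("data", con, eos = NULL)
  w_u32(data_bytes)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
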