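#' Audio segment
#'
#' Container for a single-channel sampled pressure signal.  Samples are
#' dimensionless amplitudes with a nominal range of \[-1, 1\] (clipped only
#' on WAV export); `start_time_s` places the first sample on the recording
#' clock so that detections can be reported in absolute scene time.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param start_time_s Time of the first sample in seconds (>= 0).
#' @return An object of class `audio_segment`.
#' @examples
#' a <- audio_segment(sin(2 * pi * 5 * seq(0, 1, by = 1 / 200)), 200)
#' duration(a)
#' @export
audio_segment <- function(samples, sample_rate_hz, start_time_s = 0) {
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number")
  }
  if (start_time_s < 0) stop("`start_time_s` must be non-negative")
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              length(x$samples), x$sample_rate_hz, duration(x),
              x$start_time_s))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param x An `audio_segment`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_segment"))
  length(x$samples) / x$sample_rate_hz
}

# ---- WAV I/O --------------------------------------------------------------
# Minimal RIFF/WAVE PCM reader/writer (16-bit mono), the dialect produced by
# the synthetic-scene generator.  Floats are clipped to [-1, 1] before
# quantization to int16.

#' Write an audio segment to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16-bit integers
#' (positive full scale 32767).
#'
#' @param x An `audio_segment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "audio_segment"))
  fs <- as.integer(round(x$sample_rate_hz))
  s <- pmax(-1, pmin(1, x$samples))
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path Path to a RIFF/WAVE file (PCM, 16-bit, mono).
#' @param start_time_s Start time to attach to the returned segment.
#' @return An `audio_segment` with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path, start_time_s = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      seek(con, size - 16, origin = "current")
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      samples <- readBin(con, "integer", size / 2, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      seek(con, size, origin = "current")
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (bits != 16L) stop("only 16-bit WAV supported")
  if (channels != 1L) stop("only mono WAV supported")
  audio_segment(samples / 32767, fs, start_time_s)
}

# ---- Annotation CSV -------------------------------------------------------

#' Read / write event annotation lists
#'
#' Annotations are stored as CSV with columns `onset_s,label`; onsets are
#' sorted on read.
#'
#' @param x A data frame with columns `onset_s` and `label`.
#' @param path CSV file path.
#' @return `read_annotations` returns a data frame sorted by onset.
#' @export
write_annotations <- function(x, path) {
  stopifnot(all(c("onset_s", "label") %in% names(x)))
  utils::write.csv(x[, c("onset_s", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(x))) {
    stop("annotation CSV must have columns onset_s,label")
  }
  x[order(x$onset_s), , drop = FALSE]
}
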