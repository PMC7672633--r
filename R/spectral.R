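# Short-time spectral front end of the D-call detector: 64-sample frames,
# 50% overlap (hop 32), 32 retained frequency bins (the Nyquist bin of the
# 64-point real transform is discarded), optional low-frequency masking.

#' Slice a signal into fixed-length overlapping frames
#'
#' Frames advance by `hop` samples; a trailing partial frame is discarded.
#' A signal shorter than one frame yields zero frames (not an error).
#'
#' @param x An `audio_segment` or numeric vector.
#' @param frame_len Frame length in samples (default 64).
#' @param hop Hop between frame starts in samples (default 32, 50% overlap).
#' @return A `frame_len` x `n_frames` numeric matrix (0 columns if the
#'   signal is too short).
#' @export
frame_signal <- function(x, frame_len = 64, hop = 32) {
  s <- if (inherits(x, "audio_segment")) x$samples else as.numeric(x)
  n <- length(s)
  if (n < frame_len) return(matrix(numeric(0), nrow = frame_len, ncol = 0))
  n_frames <- (n - frame_len) %/% hop + 1
  starts <- (seq_len(n_frames) - 1) * hop
  idx <- outer(seq_len(frame_len), starts, `+`)
  matrix(s[idx], nrow = frame_len)
}

#' Magnitude spectrum of one frame
#'
#' Returns the linear magnitude of the first `frame_len/2` bins of the
#' discrete Fourier transform (bins 0..31 for a 64-sample frame, covering
#' 0 up to — excluding — Nyquist).  No normalization is applied.
#'
#' @param frame Numeric vector, one frame of samples.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return Numeric vector of `length(frame)/2` magnitudes.
#' @export
magnitude_spectrum <- function(frame, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  n <- length(frame)
  if (n < 2 || n %% 2 != 0) stop("frame length must be even and >= 2")
  if (window == "hann") {
    frame <- frame * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n))
  }
  Mod(stats::fft(frame))[seq_len(n / 2)]
}

#' Short-time magnitude spectrogram
#'
#' Combines [frame_signal()] and [magnitude_spectrum()] over a whole
#' segment.  Frame times are the start times of each frame on the segment
#' clock.
#'
#' @inheritParams frame_signal
#' @inheritParams magnitude_spectrum
#' @return An object of class `spectrogram`: list with `mag`
#'   (`n_bins` x `n_frames` matrix), `bin_freqs_hz`, `frame_times_s`,
#'   `hop_s` and `sample_rate_hz`.
#' @export
spectrogram <- function(x, frame_len = 64, hop = 32,
                        window = c("rectangular", "hann")) {
  stopifnot(inherits(x, "audio_segment"))
  window <- match.arg(window)
  fr <- frame_signal(x, frame_len, hop)
  if (window == "hann") {
    fr <- fr * (0.5 - 0.5 * cos(2 * pi * (seq_len(frame_len) - 1) / frame_len))
  }
  mag <- if (ncol(fr) == 0) {
    matrix(numeric(0), nrow = frame_len / 2, ncol = 0)
  } else {
    Mod(stats::mvfft(fr))[seq_len(frame_len / 2), , drop = FALSE]
  }
  structure(
    list(mag = mag,
         bin_freqs_hz = (seq_len(frame_len / 2) - 1) *
           x$sample_rate_hz / frame_len,
         frame_times_s = x$start_time_s +
           (seq_len(ncol(mag)) - 1) * hop / x$sample_rate_hz,
         hop_s = hop / x$sample_rate_hz,
         sample_rate_hz = x$sample_rate_hz),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d frames x %d bins, hop %g s, bins %g..%g Hz\n",
              ncol(x$mag), nrow(x$mag), x$hop_s,
              min(x$bin_freqs_hz), max(x$bin_freqs_hz)))
  invisible(x)
}

#' Zero out low-frequency bins
#'
#' Removes low-frequency noise before the peak-ratio statistic: every bin
#' whose centre frequency is strictly below `cutoff_hz` is set to zero
#' (the DC bin included).  Idempotent.
#'
#' @param x A `spectrogram`, or a numeric magnitude vector (then
#'   `bin_freqs_hz` is required).
#' @param cutoff_hz Cutoff in Hz (default 20).
#' @param bin_freqs_hz Bin centre frequencies for the vector method.
#' @return Object of the same shape with masked bins zeroed.
#' @export
mask_low_freq <- function(x, cutoff_hz = 20, bin_freqs_hz = NULL) {
  if (inherits(x, "spectrogram")) {
    x$mag[x$bin_freqs_hz < cutoff_hz, ] <- 0
    return(x)
  }
  if (is.null(bin_freqs_hz)) {
    stop("`bin_freqs_hz` is required when masking a plain vector")
  }
  stopifnot(length(bin_freqs_hz) == length(x))
  x[bin_freqs_hz < cutoff_hz] <- 0
  x
}

#' Dump a spectrogram to CSV (one row per frame) for inspection
#' @param x A `spectrogram`.
#' @param path Output CSV path.
#' @export
write_spectrogram_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrogram"))
  df <- as.data.frame(t(x$mag))
  names(df) <- sprintf("f%.3f", x$bin_freqs_hz)
  df <- cbind(frame_time_s = x$frame_times_s, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
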