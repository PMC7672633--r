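# Simplified seismic P-wave trigger: causal high-pass above 1 Hz to remove
# microseismic noise, then a sample-wise STA/LTA (10 s over 100 s) on the
# absolute amplitude.  The downstream wavelet-based discrimination of the
# full float algorithm is out of scope here; the trigger emits times only.

#' Seismic trigger configuration
#'
#' @param threshold STA/LTA trigger threshold (required; the reference
#'   algorithm does not publish a value).
#' @param highpass_cutoff_hz High-pass cutoff in Hz (default 1).
#' @param sta_s,lta_s Short/long averaging windows in seconds (10 / 100).
#' @param sample_rate_hz Expected sampling rate (default 40 Hz, the low
#'   frequency hydrophone configuration).
#' @param filter_order Butterworth order of the high-pass (default 4).
#' @param stride Samples per STA/LTA evaluation block: 1 (default)
#'   evaluates per sample; 40 emulates per-packet evaluation by averaging
#'   `stride`-sample blocks first.
#' @return A list of class `seismic_config`.
#' @export
seismic_config <- function(threshold, highpass_cutoff_hz = 1,
                           sta_s = 10, lta_s = 100,
                           sample_rate_hz = 40, filter_order = 4,
                           stride = 1) {
  if (missing(threshold)) stop("`threshold` is required (no default)")
  stopifnot(threshold > 0, sta_s < lta_s,
            highpass_cutoff_hz < sample_rate_hz / 2, stride >= 1)
  structure(as.list(environment()), class = "seismic_config")
}

#' Causal Butterworth high-pass filter
#'
#' Suppresses microseismic noise below `cutoff_hz` ahead of the amplitude
#' trigger.  The filter is causal (one-pass), so a constant group delay of
#' a few samples is accepted rather than zero-phase filtering.
#'
#' @param audio An `audio_segment`.
#' @param cutoff_hz Cutoff frequency, must be below Nyquist.
#' @param order Butterworth order (default 4).
#' @return The filtered `audio_segment`.
#' @export
highpass <- function(audio, cutoff_hz = 1, order = 4) {
  stopifnot(inherits(audio, "audio_segment"))
  nyq <- audio$sample_rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop("`cutoff_hz` must lie in (0, Nyquist)")
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "high")
  y <- as.numeric(signal::filter(bf, audio$samples))
  audio_segment(y, audio$sample_rate_hz, audio$start_time_s)
}

#' Detect seismic-amplitude triggers
#'
#' High-passes the signal, computes a sample-wise STA/LTA of its absolute
#' amplitude, and reports the time of the first sample of each maximal run
#' where the statistic is at or above the threshold.
#'
#' @param audio An `audio_segment` of at least one LTA span.
#' @param cfg A [seismic_config()].
#' @return Numeric vector of trigger times in seconds (scene clock);
#'   empty, with a warning, if the audio is shorter than the LTA window.
#' @export
detect_seismic_triggers <- function(audio, cfg) {
  stopifnot(inherits(audio, "audio_segment"),
            inherits(cfg, "seismic_config"))
  fs <- audio$sample_rate_hz
  if (duration(audio) < cfg$lta_s) {
    warning("audio shorter than the LTA window; no trigger attempted")
    return(numeric(0))
  }
  hp <- highpass(audio, cfg$highpass_cutoff_hz, cfg$filter_order)
  a <- abs(hp$samples)
  step_s <- cfg$stride / fs
  if (cfg$stride > 1) {
    nb <- length(a) %/% cfg$stride
    a <- colMeans(matrix(a[seq_len(nb * cfg$stride)], nrow = cfg$stride))
  }
  sta_len <- max(1, round(cfg$sta_s / step_s))
  lta_len <- max(sta_len + 1, round(cfg$lta_s / step_s))
  s <- stalta(a, sta_len, lta_len)
  active <- s >= cfg$threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  audio$start_time_s + (starts[r$values] - 1) * step_s
}
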