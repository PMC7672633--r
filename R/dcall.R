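# Rule-based blue whale D-call detector.
#
# Per spectrogram frame, a narrow-band-ness statistic is computed: the sum
# of the two highest spectral magnitudes over the sum of the fifth and
# sixth highest.  The statistic is high only while a narrow-band signal is
# present.  An STA/LTA of the ratio curve drives a trigger state machine;
# each trigger window's peak-frequency trajectory is truncated (maximum to
# first following local minimum), its bin-to-bin transitions counted, and
# seven empirical checks decide whether the window is a D-call.

#' D-call detector configuration
#'
#' All thresholds of the detection pipeline in one place.  The seven
#' validation checks use the empirical defaults of the rule set: window
#' count > 4, mean ratio > 2.5, downward moves > 3x upward, downward > 2,
#' downward > 0.25x stable, maximum frequency > 40 Hz, and no frequency
#' change above 20 Hz across any 0.8 s span of the retained trajectory.
#'
#' The STA/LTA smoother keeps the 5/15-window geometry of the reference
#' declaration.  Because the long-term average contains the short-term
#' one, the statistic is bounded by `lta_len/sta_len` = 3 and decays as a
#' call fills the long window, so the trigger must sit between the noise
#' floor (~1, excursions to ~1.2 on Gaussian noise) and the transient
#' signal plateau; it defaults to 1.3.  Every field is overridable.
#'
#' @param frame_len,hop STFT geometry in samples (64 / 32).
#' @param window STFT window, `"rectangular"` or `"hann"`.
#' @param mask_cutoff_hz Low-frequency mask cutoff (20 Hz).
#' @param sta_len,lta_len STA/LTA window lengths in frames.
#' @param threshold Trigger threshold on the smoothed ratio curve
#'   (trigger at `>= threshold`, detrigger below it).
#' @param ratio_cap Value returned by the peak ratio when only its
#'   denominator is zero.
#' @param min_bin_separation Optional minimum bin spacing between the six
#'   selected maxima (0 = off, the default rule).
#' @param pre_trigger_frames Frames prepended to each trigger window to
#'   compensate trigger latency (0 = reference behaviour).
#' @param min_windows,min_mean_ratio,down_up_factor,min_down,
#'   down_stable_factor,min_max_freq_hz,max_jump_hz,jump_span_s Validation
#'   thresholds (see description).
#' @return A list of class `dcall_config`.
#' @export
dcall_config <- function(frame_len = 64, hop = 32,
                         window = "rectangular",
                         mask_cutoff_hz = 20,
                         sta_len = 5, lta_len = 15, threshold = 1.3,
                         ratio_cap = 100,
                         min_bin_separation = 0,
                         pre_trigger_frames = 0,
                         min_windows = 4,
                         min_mean_ratio = 2.5,
                         down_up_factor = 3,
                         min_down = 2,
                         down_stable_factor = 0.25,
                         min_max_freq_hz = 40,
                         max_jump_hz = 20,
                         jump_span_s = 0.8) {
  cfg <- as.list(environment())
  stopifnot(cfg$sta_len >= 1, cfg$lta_len > cfg$sta_len, cfg$threshold > 0)
  class(cfg) <- "dcall_config"
  cfg
}

#' Spectral peak-ratio statistic
#'
#' `(max1 + max2) / (max5 + max6)` over the six largest bin magnitudes of
#' a (already low-frequency-masked) spectrum.  The ratio is large only when
#' energy is concentrated in one or two bins, i.e. a narrow-band signal.
#' A fully zero spectrum gives 1 (flat by convention); a zero denominator
#' with non-zero numerator gives `cap`.
#'
#' The six maxima are selected iteratively (repeated `which.max` with
#' masking), which also supports an optional minimum bin separation
#' between the selected peaks.
#'
#' @param spectrum Numeric vector of >= 6 non-negative magnitudes.
#' @param cap Value returned when only the denominator vanishes.
#' @param min_bin_separation Minimum index spacing between selected maxima
#'   (0 disables the constraint).
#' @return A single non-negative ratio.
#' @examples
#' peak_ratio(c(8, 6, 5, 4, 1, 1, rep(0, 26)))  # (8+6)/(1+1) = 7
#' @export
peak_ratio <- function(spectrum, cap = 100, min_bin_separation = 0) {
  n <- length(spectrum)
  if (n < 6) stop("spectrum must have at least 6 bins")
  if (min_bin_separation == 0) {
    v <- spectrum
    sel <- numeric(6)
    for (k in 1:6) {
      j <- which.max(v)
      sel[k] <- v[j]
      v[j] <- -Inf
    }
  } else {
    v <- spectrum
    sel <- numeric(6)
    for (k in 1:6) {
      j <- which.max(v)
      if (!is.finite(v[j])) stop("too few separated bins for 6 maxima")
      sel[k] <- v[j]
      lo <- max(1, j - min_bin_separation)
      hi <- min(n, j + min_bin_separation)
      v[lo:hi] <- -Inf
    }
  }
  num <- sel[1] + sel[2]
  den <- sel[5] + sel[6]
  if (den == 0) {
    if (num == 0) 1 else cap
  } else {
    num / den
  }
}

#' Run the trigger state machine over a ratio curve
#'
#' Smooths the per-frame ratio series with [stalta()] and extracts the
#' maximal runs where the smoothed value is `>= threshold` (detrigger when
#' it drops below).  A run still open at the end of the signal is closed
#' there.  Each window carries the raw ratios and peak-frequency values of
#' its frames; `pre_trigger_frames` extra frames may be prepended.
#'
#' @param ratios Per-frame peak-ratio series.
#' @param peak_freqs_hz Per-frame peak (argmax) frequencies, same length.
#' @param cfg A [dcall_config()].
#' @return List of trigger windows: each a list with `start`, `end`
#'   (1-based frame indices), `trigger_frame` (the frame that fired),
#'   `ratios` and `peak_freqs_hz`.
#' @export
run_trigger <- function(ratios, peak_freqs_hz, cfg = dcall_config()) {
  stopifnot(length(ratios) == length(peak_freqs_hz))
  if (length(ratios) == 0) return(list())
  sm <- stalta(ratios, cfg$sta_len, cfg$lta_len)
  active <- sm >= cfg$threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(k) {
    trig <- starts[k]
    s <- max(1, trig - cfg$pre_trigger_frames)
    e <- ends[k]
    list(start = s, end = e, trigger_frame = trig,
         ratios = ratios[s:e], peak_freqs_hz = peak_freqs_hz[s:e])
  })
}

#' Truncate a peak-frequency trajectory
#'
#' Keeps the part of the trajectory between its maximum (earliest index on
#' ties) and the first local minimum after that maximum, inclusive;
#' without a later local minimum the trajectory runs to its end.  This
#' trims unreliable values at the edges of a trigger window before the
#' transition counts.
#'
#' @param freqs Non-empty numeric trajectory (Hz or bin indices).
#' @return List with `values` (the retained sub-trajectory) and
#'   `start_offset` (0-based offset of its first element in `freqs`).
#' @examples
#' truncate_trajectory(c(40, 80, 60, 40, 20, 30, 25))$values  # 80 60 40 20
#' @export
truncate_trajectory <- function(freqs) {
  n <- length(freqs)
  if (n == 0) stop("empty trajectory")
  imax <- which.max(freqs)
  iend <- n
  if (imax < n - 1) {
    for (i in (imax + 1):(n - 1)) {
      if (freqs[i] <= freqs[i - 1] && freqs[i] < freqs[i + 1]) {
        iend <- i
        break
      }
    }
  }
  list(values = freqs[imax:iend], start_offset = imax - 1)
}

#' Count downward / upward / stable frequency transitions
#'
#' Over consecutive pairs of a bin-quantized trajectory; the three counts
#' always sum to `length(freqs) - 1`.
#'
#' @param freqs Numeric trajectory (bin indices or bin frequencies).
#' @return Named integer vector `c(n_down, n_up, n_stable)`.
#' @export
count_transitions <- function(freqs) {
  if (length(freqs) < 1) stop("trajectory must be non-empty")
  d <- diff(freqs)
  c(n_down = sum(d < 0), n_up = sum(d > 0), n_stable = sum(d == 0))
}

#' Feature vector of a (truncated) trigger window
#'
#' @param ratios Ratio values of the retained frames.
#' @param peak_freqs_hz Peak-frequency values of the retained frames.
#' @param hop_s Frame hop in seconds (for the jump-span conversion).
#' @param jump_span_s Time span over which frequency jumps are measured.
#' @return A list of class `dcall_features`: `n_windows`, `mean_ratio`,
#'   `n_down`, `n_up`, `n_stable`, `max_freq_hz`, `max_jump_hz`.
#' @export
dcall_features <- function(ratios, peak_freqs_hz, hop_s,
                           jump_span_s = 0.8) {
  stopifnot(length(ratios) == length(peak_freqs_hz),
            length(ratios) >= 1)
  tr <- count_transitions(peak_freqs_hz)
  span_frames <- max(1L, floor(jump_span_s / hop_s + 1e-9))
  n <- length(peak_freqs_hz)
  max_jump <- 0
  if (n > 1) {
    for (k in seq_len(min(span_frames, n - 1))) {
      max_jump <- max(max_jump,
                      abs(peak_freqs_hz[(k + 1):n] -
                          peak_freqs_hz[seq_len(n - k)]))
    }
  }
  structure(list(n_windows = n,
                 mean_ratio = mean(ratios),
                 n_down = unname(tr["n_down"]),
                 n_up = unname(tr["n_up"]),
                 n_stable = unname(tr["n_stable"]),
                 max_freq_hz = max(peak_freqs_hz),
                 max_jump_hz = max_jump),
            class = "dcall_features")
}

#' Apply the seven D-call validation checks
#'
#' A window is accepted as a D-call only if all checks hold:
#' 1. more than `min_windows` successive windows retained (strict);
#' 2. mean ratio above `min_mean_ratio`;
#' 3. downward moves more than `down_up_factor` x upward moves;
#' 4. more than `min_down` downward moves;
#' 5. downward moves more than `down_stable_factor` x stable moves;
#' 6. maximum frequency above `min_max_freq_hz` (strict);
#' 7. no frequency change above `max_jump_hz` within `jump_span_s`.
#'
#' @param features A [dcall_features()] object.
#' @param cfg A [dcall_config()] carrying the thresholds.
#' @return List with `accepted` (logical) and `checks` (named logical 7).
#' @export
validate_dcall <- function(features, cfg = dcall_config()) {
  stopifnot(inherits(features, "dcall_features"))
  checks <- c(
    length      = features$n_windows > cfg$min_windows,
    mean_ratio  = features$mean_ratio > cfg$min_mean_ratio,
    down_vs_up  = features$n_down > cfg$down_up_factor * features$n_up,
    down_count  = features$n_down > cfg$min_down,
    down_vs_stable = features$n_down >
      cfg$down_stable_factor * features$n_stable,
    max_freq    = features$max_freq_hz > cfg$min_max_freq_hz,
    max_jump    = features$max_jump_hz <= cfg$max_jump_hz
  )
  list(accepted = all(checks), checks = checks)
}

#' Detect blue whale D-calls in an audio segment
#'
#' End-to-end pipeline: short-time spectra (64 samples, 50% overlap, 32
#' bins) -> low-frequency mask -> per-frame peak ratio and peak frequency
#' -> STA/LTA trigger -> trajectory truncation -> transition counts ->
#' seven validation checks.  Strictly causal: each frame's statistics
#' depend only on past frames.  The reported onset is the time of the
#' frame that fired the trigger.
#'
#' @param audio An `audio_segment`; content is assumed band-limited below
#'   Nyquist (200 Hz sampling is the reference configuration).
#' @param cfg A [dcall_config()].
#' @param keep_rejected Keep rejected trigger windows in the output
#'   (default TRUE; filter on `accepted` for final detections).
#' @return A data frame with one row per trigger window: `onset_s`,
#'   `accepted`, `n_windows`, `mean_ratio`, `n_down`, `n_up`, `n_stable`,
#'   `max_freq_hz`, `max_jump_hz`, `win_start_frame`, `win_end_frame`, and
#'   a `checks` attribute (logical matrix, one row per window).
#' @export
detect_dcalls <- function(audio, cfg = dcall_config(),
                          keep_rejected = TRUE) {
  stopifnot(inherits(audio, "audio_segment"))
  empty <- data.frame(onset_s = numeric(0), accepted = logical(0),
                      n_windows = integer(0), mean_ratio = numeric(0),
                      n_down = integer(0), n_up = integer(0),
                      n_stable = integer(0), max_freq_hz = numeric(0),
                      max_jump_hz = numeric(0),
                      win_start_frame = integer(0),
                      win_end_frame = integer(0))
  min_len <- cfg$frame_len + (cfg$lta_len - 1) * cfg$hop
  if (length(audio$samples) < min_len) {
    warning("audio shorter than one LTA span; no detection attempted")
    return(empty)
  }
  sp <- spectrogram(audio, cfg$frame_len, cfg$hop, cfg$window)
  sp <- mask_low_freq(sp, cfg$mask_cutoff_hz)
  n_frames <- ncol(sp$mag)
  ratios <- numeric(n_frames)
  peak_bin <- integer(n_frames)
  for (i in seq_len(n_frames)) {
    col <- sp$mag[, i]
    ratios[i] <- peak_ratio(col, cfg$ratio_cap, cfg$min_bin_separation)
    peak_bin[i] <- which.max(col)
  }
  peak_hz <- sp$bin_freqs_hz[peak_bin]
  wins <- run_trigger(ratios, peak_hz, cfg)
  if (length(wins) == 0) return(empty)
  rows <- lapply(wins, function(w) {
    tr <- truncate_trajectory(w$peak_freqs_hz)
    idx <- seq.int(tr$start_offset + 1, length.out = length(tr$values))
    feats <- dcall_features(w$ratios[idx], tr$values, sp$hop_s,
                            cfg$jump_span_s)
    v <- validate_dcall(feats, cfg)
    list(row = data.frame(onset_s = sp$frame_times_s[w$trigger_frame],
                          accepted = v$accepted,
                          n_windows = feats$n_windows,
                          mean_ratio = feats$mean_ratio,
                          n_down = feats$n_down, n_up = feats$n_up,
                          n_stable = feats$n_stable,
                          max_freq_hz = feats$max_freq_hz,
                          max_jump_hz = feats$max_jump_hz,
                          win_start_frame = w$start,
                          win_end_frame = w$end),
         checks = v$checks)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  checks <- do.call(rbind, lapply(rows, `[[`, "checks"))
  if (!keep_rejected) {
    keep <- out$accepted
    out <- out[keep, , drop = FALSE]
    checks <- checks[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "checks") <- checks
  out
}
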