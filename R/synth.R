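# Seeded generator of synthetic hydrophone scenes: Gaussian background
# noise, D-call-like downward chirps and broadband seismic-like transients,
# with ground-truth annotations.  All randomness is drawn from a local RNG
# state so generation is reproducible and does not disturb the caller's
# random stream.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate Gaussian background noise
#'
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param rms_level Target RMS amplitude (>= 0); the standard deviation of
#'   the Gaussian samples.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An `audio_segment`.
#' @export
gen_noise <- function(duration_s, sample_rate_hz, rms_level, seed = NULL) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive")
  if (rms_level < 0) stop("`rms_level` must be non-negative")
  n <- round(duration_s * sample_rate_hz)
  s <- if (rms_level == 0) numeric(n) else
    with_local_seed(seed, stats::rnorm(n, sd = rms_level))
  audio_segment(s, sample_rate_hz)
}

#' Generate a D-call-like downward frequency sweep
#'
#' A narrow-band chirp whose instantaneous frequency falls from
#' `f_start_hz` to `f_end_hz` over `duration_s`, emulating the downward
#' sweep (typically 80 to 20 Hz) of blue whale D-calls.  The sweep is
#' linear in time by default; `curvature` bends it (instantaneous frequency
#' `f_start + (f_end - f_start) * (t/D)^curvature`).  A raised-cosine taper
#' over the first and last `taper_frac` of the call avoids onset clicks.
#'
#' @param onset_s Call onset on the scene clock, seconds.
#' @param duration_s Call duration, seconds.
#' @param f_start_hz,f_end_hz Sweep start/end frequency in Hz; must satisfy
#'   `f_start_hz > f_end_hz >= 0` and both below Nyquist.
#' @param amplitude Peak amplitude of the chirp.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param curvature Sweep-law exponent; 1 = linear.
#' @param taper_frac Fraction of the call faded in/out (default 0.1).
#' @return An `audio_segment` starting at `onset_s`.
#' @export
gen_dcall <- function(onset_s, duration_s, f_start_hz = 80, f_end_hz = 20,
                      amplitude = 1, sample_rate_hz = 200,
                      curvature = 1, taper_frac = 0.1) {
  nyq <- sample_rate_hz / 2
  if (!(f_start_hz > f_end_hz && f_end_hz >= 0)) {
    stop("need `f_start_hz` > `f_end_hz` >= 0 (downward sweep)")
  }
  if (f_start_hz >= nyq) stop("`f_start_hz` must be below Nyquist")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  u <- t / duration_s
  # phase = 2*pi * integral of f(t) dt for f = f0 + (f1-f0) u^curvature
  phase <- 2 * pi * (f_start_hz * t +
    (f_end_hz - f_start_hz) * duration_s * u^(curvature + 1) / (curvature + 1))
  s <- amplitude * sin(phase)
  nt <- max(1, round(taper_frac * n))
  if (nt > 1 && n >= 2 * nt) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 1) / (nt - 1)))
    s[seq_len(nt)] <- s[seq_len(nt)] * ramp
    s[n - seq_len(nt) + 1] <- s[n - seq_len(nt) + 1] * ramp
  }
  audio_segment(s, sample_rate_hz, start_time_s = onset_s)
}

#' Generate a seismic-like low-frequency transient
#'
#' A burst of band-limited noise with an exponentially decaying envelope,
#' emulating the abrupt amplitude increase of a P-wave arrival.
#'
#' @inheritParams gen_dcall
#' @param f_hz Centre frequency of the burst, Hz.
#' @param decay_s Envelope e-folding time, seconds.
#' @param seed Integer seed for the in-burst noise.
#' @return An `audio_segment` starting at `onset_s`.
#' @export
gen_transient <- function(onset_s, duration_s, amplitude = 1,
                          sample_rate_hz = 40, f_hz = 5, decay_s = NULL,
                          seed = NULL) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (f_hz >= sample_rate_hz / 2) stop("`f_hz` must be below Nyquist")
  if (is.null(decay_s)) decay_s <- duration_s / 3
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  carrier <- with_local_seed(seed, {
    ph <- stats::runif(1, 0, 2 * pi)
    jitter <- stats::rnorm(n, sd = 0.3)
    sin(2 * pi * f_hz * t + ph) + jitter
  })
  env <- exp(-t / decay_s)
  env[1:max(1, round(0.02 * n))] <-
    seq(0, 1, length.out = max(1, round(0.02 * n)))  # sharp but finite rise
  audio_segment(amplitude * env * carrier, sample_rate_hz,
                start_time_s = onset_s)
}

#' Describe a synthetic event for scene assembly
#'
#' @param kind `"dcall"` or `"transient"`.
#' @param onset_s Event onset in seconds.
#' @param duration_s Event duration in seconds.
#' @param f_start_hz,f_end_hz Sweep endpoints (D-calls only).
#' @param amplitude Peak amplitude.
#' @param ... Extra arguments passed to the per-kind generator.
#' @return A list of class `synthetic_event`.
#' @export
synthetic_event <- function(kind = c("dcall", "transient"), onset_s,
                            duration_s, f_start_hz = 80, f_end_hz = 20,
                            amplitude = 1, ...) {
  kind <- match.arg(kind)
  if (kind == "dcall" && !(f_start_hz > f_end_hz)) {
    stop("D-calls sweep downward: need `f_start_hz` > `f_end_hz`")
  }
  structure(list(kind = kind, onset_s = onset_s, duration_s = duration_s,
                 f_start_hz = f_start_hz, f_end_hz = f_end_hz,
                 amplitude = amplitude, extra = list(...)),
            class = "synthetic_event")
}

#' Assemble a synthetic hydrophone scene with ground truth
#'
#' Sums seeded Gaussian noise with the waveforms of the given events and
#' returns the mixed scene together with an annotation table (one row per
#' event, `onset_s` and `label`).  Events may overlap; an event running past
#' the end of the scene is an error.
#'
#' @param events List of [synthetic_event()] objects (possibly empty).
#' @param duration_s Scene duration in seconds.
#' @param sample_rate_hz Scene sampling rate in Hz.
#' @param noise_rms RMS of the background noise.
#' @param seed Integer seed controlling the noise and any stochastic events.
#' @return A list with elements `audio` (an `audio_segment`) and
#'   `annotations` (a data frame `onset_s,label`).
#' @export
gen_scene <- function(events, duration_s, sample_rate_hz = 200,
                      noise_rms = 0.05, seed = 1) {
  noise <- gen_noise(duration_s, sample_rate_hz, noise_rms, seed = seed)
  s <- noise$samples
  n <- length(s)
  ann <- data.frame(onset_s = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  for (k in seq_along(events)) {
    ev <- events[[k]]
    stopifnot(inherits(ev, "synthetic_event"))
    if (ev$onset_s < 0 || ev$onset_s + ev$duration_s > duration_s) {
      stop(sprintf("event %d (%s at %g s) exceeds the scene duration",
                   k, ev$kind, ev$onset_s))
    }
    w <- switch(ev$kind,
      dcall = do.call(gen_dcall, c(list(ev$onset_s, ev$duration_s,
                                        ev$f_start_hz, ev$f_end_hz,
                                        ev$amplitude, sample_rate_hz),
                                   ev$extra)),
      transient = do.call(gen_transient,
                          c(list(ev$onset_s, ev$duration_s, ev$amplitude,
                                 sample_rate_hz),
                            ev$extra,
                            list(seed = if (is.null(seed)) NULL
                                 else seed + k)))
    )
    i0 <- round(ev$onset_s * sample_rate_hz) + 1
    idx <- i0:min(n, i0 + length(w$samples) - 1)
    s[idx] <- s[idx] + w$samples[seq_along(idx)]
    ann <- rbind(ann, data.frame(onset_s = ev$onset_s, label = ev$kind,
                                 stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  list(audio = audio_segment(s, sample_rate_hz), annotations = ann)
}

#' Build a scene from a recipe list (as loaded from YAML)
#'
#' The recipe mirrors the scene-generator arguments:
#' `duration_s`, `sample_rate_hz`, `noise_rms`, `seed`, and `events`, a list
#' of per-event maps with the [synthetic_event()] fields.
#'
#' @param recipe A named list (e.g. `yaml::read_yaml()` output).
#' @param seed Optional override of the recipe seed.
#' @return As [gen_scene()].
#' @export
scene_from_recipe <- function(recipe, seed = NULL) {
  events <- lapply(recipe$events, function(e) do.call(synthetic_event, e))
  gen_scene(events,
            duration_s = recipe$duration_s,
            sample_rate_hz = recipe$sample_rate_hz %||% 200,
            noise_rms = recipe$noise_rms %||% 0.05,
            seed = seed %||% recipe$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
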