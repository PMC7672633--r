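---
title: "Detecting blue whale D-calls and budgeting float resources with floatcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting blue whale D-calls and budgeting float resources with floatcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floatcall)
```

# Scope and model

`floatcall` implements two signal-processing applications of
hydrophone-equipped profiling floats — a blue whale D-call detector and a
simplified seismic amplitude trigger — together with the static models
used to verify that such applications fit a float's processor, battery
and satellite budget. This vignette documents the science and the design
decisions; every number quoted here is computed by the package's tests or
examples, not asserted.

# The D-call detector

A D-call is a narrow-band vocalization sweeping downward, typically from
about 80 Hz to 20 Hz, over a few seconds. The detector exploits exactly
two properties: the signal is *narrow-band* at any instant, and its peak
frequency *falls* over time.

## Spectral front end

The signal (nominally sampled at 200 Hz, so that the 0–100 Hz band of
interest fills the spectrum) is cut into 64-sample frames advancing by 32
samples (50% overlap). Each frame yields the linear magnitude of the
first 32 bins of its discrete Fourier transform — bin spacing
`sample_rate/64`, i.e. 3.125 Hz at 200 Hz — and the Nyquist bin is
discarded. The default window is rectangular: the statistic below is a
ratio of order statistics of the same spectrum, so window choice has
little effect, and the rectangular window matches the minimal arithmetic
an embedded implementation would use; a Hann window is available by
argument. No FFT normalization is applied — the ratio is invariant to it.
Bins whose centre frequency lies below 20 Hz are zeroed before any
statistic is computed, removing low-frequency flow and vessel noise (the
DC bin is always zeroed at this default).

## Peak ratio and trigger

Per frame, with `v1 >= v2 >= ... >= v6` the six largest bin magnitudes,
the detector computes `r = (v1 + v2)/(v5 + v6)`. For broadband noise all
order statistics are comparable and `r` stays near 1–2; a narrow-band
component lifts one or two bins far above the fifth and sixth, so `r`
rises sharply. Degenerate cases are fixed by convention: an all-zero
spectrum gives 1 (flat), and a zero denominator with non-zero numerator
returns a configurable cap (default 100) rather than infinity so that
downstream averages stay finite. The six maxima are selected without any
adjacency constraint by default; a minimum bin-separation option exists
but is off, since the rule set defines the statistic on plain order
statistics.

The ratio curve is smoothed by a short-term over long-term average:
`STA/LTA[i] = mean(r[i-4..i]) / mean(r[i-14..i])` with 5- and 15-frame
windows. During warm-up the available prefix feeds both means, so no
frame is ever dropped. Two consequences of this inclusive geometry shape
the trigger design:

* the statistic is bounded above by `lta_len/sta_len = 3`, and equals 1 on
  stationary input;
* once a call has filled the long window the statistic decays back toward
  1 (after `k` high-ratio frames it is roughly `15/k` for strong calls),
  so windows close on their own and any threshold of 1.88 or more would
  cap windows at four frames — too short for the length check below.

The default trigger threshold is therefore **1.3**: on seeded Gaussian
noise the smoothed ratio stays below about 1.2 over tens of thousands of
frames, while a high-SNR sweep holds the statistic above 1.3 for on the
order of ten frames. The trigger opens at `STA/LTA >= threshold` and
closes strictly below it (the boundary is assigned to the open state); a
window still open at end of signal is closed there. All trigger
parameters are configuration-first — on real recordings they should be
re-tuned on annotated data, which is also how the default was chosen on
the synthetic scenes. A pre-trigger buffer (default 0 frames) can prepend
context to each window, since the trigger necessarily lags the true call
onset by the few frames the short average needs to fill.

## Trajectory truncation, transitions and the seven checks

Each trigger window carries, per frame, the raw ratio and the frequency
of the maximum-magnitude bin of the masked spectrum (masked, because the
low bins are noise by assumption). The frequency trajectory is truncated
to the part between its maximum (earliest on ties) and the first local
minimum after it — a point no lower than its predecessor's successor and
strictly below its successor — or to the end if none exists. This trims
unreliable frames at the window edges. Transition counts (down, up,
stable) are then taken over consecutive pairs of the truncated, bin-
quantized trajectory; they always sum to one less than its length.

A window is accepted as a D-call only if all seven empirical checks hold
(all thresholds configurable, strict inequalities as listed):

1. more than 4 retained windows;
2. mean ratio above 2.5 (over the truncated part — the truncation exists
   precisely to remove unreliable values, so the mean uses what remains);
3. downward moves more than 3x upward moves;
4. more than 2 downward moves;
5. downward moves more than 0.25x stable moves;
6. maximum frequency above 40 Hz;
7. no frequency change exceeding 20 Hz between any two retained points at
   most 0.8 s apart (0.8 s is converted to frames through the hop, the
   only reading well-defined at arbitrary sample rates).

The reported onset is the time of the frame that fired the trigger. The
pipeline is strictly causal and homogeneous of degree zero in amplitude:
scaling the audio by any positive constant changes nothing, which the
test suite asserts over random scale factors.

# The seismic trigger

The companion application detects abrupt amplitude increases, the
signature of a P-wave arrival at the hydrophone: a causal 4th-order
Butterworth high-pass above 1 Hz suppresses microseismic noise, and the
same STA/LTA operator — one implementation, two callers — runs
sample-wise on the absolute amplitude with 10 s and 100 s windows. A
trigger time is the first sample of each maximal run at or above the
threshold. The threshold is deliberately a *required* parameter: no
reference value exists for it, and the appropriate value depends on site
noise. The downstream wavelet-based discrimination stage of operational
floats is out of scope. Per-packet evaluation (40-sample blocks) is
available through a stride option that averages blocks before the
STA/LTA; the default is per-sample.

# Synthetic scenes and what the tests show

The generator emulates three ingredients, each seeded and bit-for-bit
reproducible: Gaussian background noise at a requested RMS; D-call chirps
with a linear-in-time frequency law (the simplest law consistent with a
"sweep"; an exponent parameter bends it), a raised-cosine fade over the
first and last 10% against onset clicks, and defaults of 4 s duration and
an 80→20 Hz sweep; and seismic-like transients (noisy 5 Hz carrier, sharp
rise, exponential decay with e-folding a third of the duration). Scenes
are sums of noise and events with a ground-truth annotation table, and
round-trip through 16-bit PCM mono WAV within quantization error.

The reference detector condition used throughout the tests is 20
high-SNR calls (amplitude 0.5 over noise RMS 0.05, about 17 dB) in 30
minutes at 200 Hz; the suite requires event-based precision 1.0 and
recall at least 0.9 under a 6 s onset collar, and zero accepted
detections on both pure noise and a constant 60 Hz tone (narrow-band, so
it can trigger, but its flat trajectory fails the downward-transition
checks). These scenes contain stationary Gaussian noise only — no
shipping noise, propagation loss, multipath or overlapping choruses — so
passing them demonstrates the mechanics of the rule set, not field
performance; published evaluations on real annotated data observe high
precision with recall nearer one half, and the trigger coefficients must
be refit per dataset.

# Evaluation protocol

Detections are scored against annotations on onsets only: a detection is
a true positive if it falls within a collar (default ±6 s, optionally
asymmetric) of a still-unmatched annotation; matching is greedy
nearest-first in time order, mirroring common sound-event-detection
scorers, with an exact maximum-cardinality matching available by flag.
The tests verify the greedy count never exceeds, and the exact method
attains, a brute-force optimum; precision is defined as 1 with no
detections and recall as 1 with no annotations.

# Resource models

**Processor.** Each continuous acquisition mode is a periodic task with
period `input_array_len / sampling_hz` (e.g. 40 samples at 40 Hz → 1 s)
and worst-case execution time summed over its function calls; short modes
run at their coordinator period (at least one minute). Utilization
`U = sum(C_i/T_i)` is compared with the Liu–Layland bound
`n(2^{1/n} - 1)` — 100% for one task, 83% for two, 76% for four, tending
to 69% — which is sufficient-only; the test suite cross-checks it against
an exact event-driven simulation of preemptive rate-monotonic scheduling
over one hyperperiod.

**Dive timing.** Ascent requests are modelled as a Poisson process with
`lambda = rate x max_parking`; the mean parking duration is
`(1/rate)(1 - e^{-rate * max_parking})`, the mean inter-request interval
times the probability of at least one request. That expression is also
the exact expectation of `min(Exponential(rate), max_parking)`, so no
separate "exact" variant is needed — the first-moment reading and the
censored expectation coincide. Descent and ascent last `depth/speed`;
the surface stage is a constant one hour by default.

**Sensors and energy.** Intermittent activations are merged by interval
union over the hyperperiod of their periods, phase-aligned at zero and
starting active (2 min/5 min with 1 min/3 min repeats every 15 min, 9 min
active, duty 0.6). Stage energy is `Eact + Esens + Eboard + Ecom`:
actuators cost a small constant on descent, nothing at parking, and
`pump_coeff x depth^2 + surface_fill` on ascent — the quadratic
depth-power relation is the stated model, with the coefficient
user-supplied; sensors cost `power x duty x stage time`; the board its
constant power; and satellite transmission, surface-only,
`tx_bytes / tx_speed x sat_power`. Expected transmission volume sums
`bytes x branch probability x expected calls per dive`, normalized to
30-day months. Lifetime is `Ebat / Edive x Tdive`, reported in Julian
years (365.25 d). No hardware constant is defaulted: board, sensor, pump
and satellite figures vary by build and are required configuration, with
an example profile in the tests and README; headline lifetime numbers
are therefore only as good as the supplied constants.

**Composition.** Two applications can share a float only if dive depth
and maximum duration agree and a sensor shared within a stage has one
sampling rate; conflicts are returned as data, and the combined task set
is re-checked against the bound at its new cardinality.

# Numerical choices and degenerate inputs

* Frame counts follow `floor((N - 64)/32) + 1`; signals shorter than a
  frame give an empty spectrogram, and audio shorter than one LTA span
  returns no detections with a warning.
* STA/LTA returns 0 where the long-term mean is zero (signal absent), and
  handles warm-up with prefix means.
* Ties: the trajectory maximum takes the earliest index; the local-minimum
  scan takes the first qualifying point.
* `merge_activation` requires commensurate periods (it searches a bounded
  integer multiple of the longest period for the hyperperiod).
* WAV export clips to [−1, 1] before 16-bit quantization.

# Problem sizes

The test and acceptance workloads are sized for interactive runs: the
detector scenes span 2–30 minutes of 200 Hz audio (up to ~11,000 frames,
well under a second to process), seismic fixtures 400–600 s at 40 Hz, and
the oracle sweeps hundreds to a thousand random instances per property.

# Known limitations

* The detector's defaults are tuned on synthetic scenes; real-data recall
  depends strongly on SNR and on STA/LTA settings that must be refit.
* The scene generator does not model realistic ocean soundscapes.
* The seismic discrimination stage (wavelet bands, reference
  distributions, SNR decision) is not implemented; the trigger only.
* Resource reports are static worst-case/first-moment models: no
  simulation of memory, of scheduling jitter, or of depth-dependent float
  dynamics beyond the quadratic pump law.
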