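# floatcall

Rule-based detection of blue whale D-calls in hydrophone audio, plus the
static resource models needed to decide whether such a detector can run for
years on an autonomous profiling float.

## The problem

Blue whales emit a downward-sweeping, narrow-band vocalization — the
D-call — that typically glides from about 80 Hz down to 20 Hz over a few
seconds. Counting these calls in situ, on a float drifting at depth, is
attractive because satellite bandwidth is far too scarce to upload raw
audio; but it means the detector must run in real time on a
microcontroller-class processor and sip energy from a fixed battery.
`floatcall` implements both halves of that problem for R users:

* a **D-call detector** light enough to be frame-by-frame causal, built
  from short-time spectra, a spectral peak-ratio statistic, STA/LTA
  trigger logic and a set of empirical validation checks;
* a simplified **seismic P-wave trigger** (high-pass above 1 Hz, 10 s/100 s
  STA/LTA on absolute amplitude), the classical companion application of
  hydrophone floats;
* **resource models** — rate-monotonic processor utilization against the
  Liu–Layland bound, a Poisson model of dive duration, sensor-activation
  merging, satellite transmission volume, per-stage energy budgets and
  battery lifetime — and compatibility checks for composing two
  applications on one float;
* a **seeded synthetic-scene generator** (ocean-like Gaussian noise,
  D-call chirps, seismic-like transients) with ground-truth annotations,
  and **event-based scoring** under an onset collar, so the whole pipeline
  is testable without any field recording.

## The detector in brief

For each 64-sample frame (50% overlap) of the, nominally 200 Hz, signal
the detector computes the 32-bin magnitude spectrum `S`, zeroes bins below
20 Hz, and forms the peak ratio

    r = (max1(S) + max2(S)) / (max5(S) + max6(S)),

which is large only while a narrow-band signal is present. The ratio curve
is smoothed with a short-term/long-term average, `STA/LTA = mean(last 5
frames) / mean(last 15 frames)`; a trigger opens while the smoothed value
is at or above a threshold and the frames in between carry the raw ratios
and the frequency of the spectral argmax. After detriggering, the peak
frequency trajectory is truncated between its maximum and the first local
minimum after it, its bin-to-bin transitions are counted, and seven checks
must all pass — more than 4 retained windows; mean ratio above 2.5;
downward moves more than 3x upward moves, more than 2, and more than
0.25x stable moves; maximum frequency above 40 Hz; no change above 20 Hz
within 0.8 s — before the trigger time is recorded as a detection.

## Worked example

Three synthetic D-calls in ten minutes of noise, detected and scored:

```r
library(floatcall)

scene <- gen_scene(
  events = lapply(c(120, 300, 480), function(t0)
    synthetic_event("dcall", onset_s = t0, duration_s = 4,
                    f_start_hz = 80, f_end_hz = 20, amplitude = 0.5)),
  duration_s = 600, sample_rate_hz = 200, noise_rms = 0.05, seed = 1)

det <- detect_dcalls(scene$audio)
subset(det, accepted)
#>   onset_s accepted n_windows mean_ratio n_down n_up n_stable max_freq_hz
#> 1   120.0     TRUE        10      6.313      7    0        2       78.12
#> 2   300.2     TRUE         9      7.222      6    0        2       75.00
#> 3   480.2     TRUE         9      6.108      6    0        2       75.00

match_events(subset(det, accepted)$onset_s, scene$annotations$onset_s,
             collar_s = 6)
#> <match_result> TP 3  FP 0  FN 0  precision 1.000  recall 1.000
```

Each row is one trigger window: the onset (time of the frame that fired
the trigger, within a fraction of a second of the true call start), the
number of retained spectrogram windows, the mean peak ratio (well above
the 2.5 floor), the transition counts of the falling frequency trajectory
(7 down, 0 up), its maximum frequency and its largest 0.8 s frequency
jump. All three calls are matched within the 6 s onset collar.

Static analysis of a mission running that detector at 1500 m with two
ascent requests per week and an example hardware profile:

```r
report <- analyze_mission(spec)   # see ?analyze_mission for the spec shape
report
#> <resource_report>
#>   processor: U = 0.6250% of capacity, LL bound 100.0% (n=1) -> schedulable
#>   dive: parking 3.30 d (lambda 2.86, P(>=1 ascent) 0.94), total 3.69 d
#>   satellite: 4800 B/dive, 39047 B/month
#>   energy: 35.26 Wh/dive -> lifetime 1.15 years
```

The processor runs the 0.16 s-period acquisition task at a fraction of a
percent of capacity; the Poisson model turns the 10-day maximum parking
duration and the 2/7-per-day request rate into a 3.3-day mean parking
stage; transmission volume, per-stage energies and battery lifetime follow
from the (user-supplied) hardware constants.

A thin command-line wrapper covers the same workflows
(`inst/scripts/floatcall synth | detect-dcall | detect-seismic | evaluate
| analyze-mission | compose`), writing a `.meta.json` sidecar with the
full configuration next to every output.

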