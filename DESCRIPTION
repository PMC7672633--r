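Package: floatcall
Title: Blue Whale D-Call Detection and Resource Models for Hydrophone Floats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of blue whale D-calls (narrow-band downward
    frequency sweeps, typically 80 to 20 Hz) in single-channel hydrophone
    audio, built from a 64-sample short-time Fourier front end, a spectral
    peak-ratio statistic, STA/LTA (short-term average over long-term average)
    trigger logic and a set of empirical validation checks on the peak
    frequency trajectory.  Also provides a simplified seismic P-wave
    amplitude trigger, event-based scoring of detections against annotations
    under an onset collar, a seeded generator of synthetic hydrophone scenes
    with ground truth, and static resource models for autonomous profiling
    floats: rate-monotonic processor utilization with the Liu-Layland bound,
    Poisson dive-duration estimation, periodic sensor-activation merging,
    satellite transmission volume and battery lifetime budgets, and
    compatibility checks for composing applications on one float.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
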