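Package: grfcomp
Title: Ground Reaction Force Compensation for Instrumented Treadmills
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns an ordinary instrumented treadmill into a force treadmill in
    software. Identifies the linear force-transmission dynamics between the
    track surface and under-frame load cells from impact-hammer trials (raw
    spectral ratio or H1 ensemble averaging with coherence), reconstructs the
    true vertical ground reaction force by regularized inversion of the
    identified transfer function, and quantifies reconstruction fidelity with a
    waveform-error-energy total harmonic distortion metric and the 98 percent
    bandwidth statistic. Includes closed-form second-order structural models
    for benchmarking indirect-measurement force treadmills, a zero-phase
    Butterworth acquisition filter, and a synthetic-data generator for
    hammer-strike identification and walk-on-the-spot evaluation trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
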