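Package: icalternans
Title: Beat-to-Beat Alternans Analysis of Voltage-Clamp Calcium Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of whole-cell voltage-clamp recordings of
    L-type calcium currents in cardiomyocytes. Reads sweep-train recordings
    from plain-text exports, preprocesses them (energy-calibrated moving
    average smoothing, command-voltage snapping), extracts per-sweep
    electrophysiological features (capacitive, calcium and tail current
    peaks, trapezoidal charge areas, single- and double-exponential decay
    time constants with AIC model selection), and quantifies beat-to-beat
    alternans with a normalized alternation index. Includes a circuit-level
    simulator of the patch-clamp experiment (one-compartment passive cell,
    Bessel acquisition filter, parametric ionic currents with analytic
    ground truth, calibrated Gaussian noise) for validation, plus
    non-parametric group statistics for comparing uniform and alternating
    cell populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
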