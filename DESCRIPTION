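Package: sutureskill
Title: Objective Suturing-Skill Metrics from Multimodal Simulator Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for bench-top suturing simulators that log
    synchronized force/torque (1 kHz), wrist orientation (200 Hz), capacitive
    touch contact, and vision-derived needle-event annotations. Segments each
    radial stitch into active suturing and idle time, conditions force/torque
    channels with a zero-phase Butterworth low-pass filter, computes peak,
    peak-to-peak, impulse-like and consistency functionals per channel, rotates
    horizontal forces into stitch-aligned orthogonal/tangential components from
    image-derived stitch geometry, counts physical touches, and compares
    attending versus resident cohorts with Lilliefors screening and Wilcoxon
    rank-sum tests. Includes a synthetic-bench generator with per-stitch ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    data.table,
    tibble,
    dplyr,
    nortest,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
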