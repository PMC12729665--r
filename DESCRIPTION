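Package: qusfat
Title: Differential Estimation of Subcutaneous and Intermuscular Fat from
    Through-Transmission Quantitative Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differential assessment of subcutaneous (SAT) and
    intermuscular (IMAT) adipose fractions from through-transmission ultrasound
    signal trains. Provides a calibrated phantom-signal simulator (tone bursts at
    0.8 and 2.2 MHz plus a 0.5-2.5 MHz sweep over a 5x5 SAT-by-IMAT phantom grid),
    extraction of six acoustic evaluation criteria (velocity, attenuations, their
    ratio, sweep intensity, direct-to-triple-pass ratio), a min-max decision-surface
    pattern-recognition estimator with Akima-densified envelope surfaces and
    feasible-region intersection, a gated neural-network regression baseline, and
    the split-based evaluation protocol with individuality and regression metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
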