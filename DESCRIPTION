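Package: nfkbosc
Title: Quantitative Analysis of NF-kB Nuclear Translocation and Oscillations
Version: 0.1.0
Authors@R:
    person("Plate", "Watcher", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying NF-kB (p65) nuclear translocation from
    two-channel high-content microscopy and for modelling its dynamics.
    Includes a seeded synthetic microscopy generator with per-cell ground
    truth, nucleus segmentation with eroded-nucleus and cytoplasmic-ring
    compartments, feature gating and per-well percentage statistics, a
    one-variable delay differential equation model of the IkBa negative
    feedback loop, multiplicity-of-infection dependent population
    simulations, and single-cell trace analysis (peak detection, peak-to-peak
    interval statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
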