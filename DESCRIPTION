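Package: flimsim
Title: Simulation and Power Analysis of Fluorescence Lifetime Data in
    Biological Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulation of time-correlated single-photon-counting
    (TCSPC) fluorescence lifetime histograms as acquired from biosensors in
    biological tissue, including instrument response function (IRF)
    convolution, tissue autofluorescence, photomultiplier afterpulse, and
    background signal.  Provides the two standard lifetime readouts
    (empirical lifetime and fixed-tau double-exponential fitting by
    Gauss-Newton least squares), minimum-detectable-difference power
    analysis, sensor-expression tolerance analysis, detector comparison,
    and intensity deconvolution of two lifetime-multiplexed sensors with
    statistical power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
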