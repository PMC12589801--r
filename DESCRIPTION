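Package: pbctmicro
Title: Microdosimetric Analysis Pipeline for Proton Boron Capture Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for silicon-on-insulator (SOI)
    microdosimetry of monoenergetic proton beams with an optional boron
    alpha-particle admixture from the p + 11B -> 3-alpha capture reaction.
    Provides alpha-particle range-energy interpolation and gap-transmission
    modelling, parameterized depth profiles of dose-averaged lineal energy,
    a seeded generator of synthetic detector data (voltage traces, peak
    amplitude lists, lineal-energy event lists), the oscilloscope-to-lineal-
    energy measurement chain (noise thresholding, peak extraction, linear
    calibration by quantile matching, 0.5 keV/um spectral binning, and Monte
    Carlo propagation of calibration uncertainty), microdosimetric statistics
    (frequency-mean and dose-averaged lineal energy, Welch comparisons), and
    an orchestrator for depth-scan and boron-comparison studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml
Config/testthat/edition: 3
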