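Package: tonomatch
Title: Cochlear-Implant Frequency-to-Place Mismatch Modelling and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling the tonotopic consequences of cochlear-implant
    electrode placement. Estimates cochlear duct length from basal-turn
    measurements (elliptic-circular approximation), converts between angular
    insertion depth and arc length along the lateral wall and organ of Corti,
    maps cochlear place to characteristic frequency with the Greenwood
    function, quantifies per-contact frequency-to-place mismatch in semitones
    with a fourth-order polynomial summary at the mid-array contact (C6), and
    relates mismatch to longitudinal speech-perception outcomes through
    covariate-adjusted partial correlations with Bonferroni control. Includes
    a seeded synthetic-cohort generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
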