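Package: thermocline
Title: Local Adaptation Tests and Thermal Vulnerability Metrics Along
    Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing local adaptation of critical thermal limits
    in structured populations via Pst-Fst comparisons, and for quantifying
    thermal vulnerability from microclimate and macroclimate data.
    Implements the Weir-Cockerham theta estimator for multi-allelic markers
    with GENEPOP input, one-way REML variance components and Pst over a
    c/h2 ratio grid with bootstrap confidence intervals, Mantel matrix
    tests, datalogger time-series summaries restricted to population
    phenology windows, warming/cooling tolerance margins, acclimation
    response ratios, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
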