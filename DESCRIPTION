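Package: crocallometry
Title: Allometric Size, Mass and Bite-Force Estimation for Crocodilians
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chained log10-log10 allometric regression for estimating body
    dimensions of crocodilians from a single skull measurement. Fits
    ordinary least-squares power-law models to calibration panels of extant
    crocodilian measurements, attaches nonparametric bootstrap confidence
    intervals and standard errors to the coefficients, and produces
    natural-scale point predictions with 95% prediction limits. A four-stage
    inference chain (skull length to snout-vent length to total length to
    body mass to bite force) supports both freshly fitted models and
    published coefficient sets, and a feeding-ecology module converts body
    mass into seasonal daily food intake via ratio constants for Nile
    crocodiles. Includes a synthetic calibration-panel generator for
    testing, report writers, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
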