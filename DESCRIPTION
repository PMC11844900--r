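Package: pehresponse
Title: Post-Exercise Central and Brachial Blood-Pressure Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for post-exercise hypotension crossover trials
    measuring central (tonometry-derived) and brachial blood pressure. Computes
    derived hemodynamic quantities (mean arterial pressure, pulse pressures,
    amplification pressure, carotid-femoral pulse wave velocity, TRIMP session
    load), classifies each participant's post-exercise systolic change as a
    hypotensive responder, hypertensive responder, non-responder or undecided
    using a region-of-practical-equivalence (ROPE) plus highest-density-interval
    (HDI) decision rule scaled by the technical error of measurement, and
    summarises group-level responses via cell summaries, marginal-mean
    contrasts, Welch tests and Hedges' g. Includes a synthetic-cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl,
    yaml,
    jsonlite
Config/testthat/edition: 3
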