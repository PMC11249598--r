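Package: bioclock
Title: Biological Age Prediction from Time-to-Event Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts biological age from left-truncated, right-censored
    cohort data using accelerated failure time (AFT) survival models on the
    chronological-age timescale. Conditional residual-life predictions from a
    fitted Gompertz AFT model (or a semiparametric Cox model) are converted to
    biological age by inversion of a reference life table. Includes a
    Cox-based comparator that rescales its linear predictor to the training
    cohort's age distribution, a prospective-cohort simulator with known true
    biological ages under Gompertz and Weibull mechanisms, and evaluation
    tools: root-mean-square error against truth, inverse-probability-of-
    censoring-weighted concordance, life-table calibration, and
    age-acceleration hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
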