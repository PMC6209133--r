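Package: sbhmort
Title: Indirect Age-Specific Child Mortality Trends from Summary Birth
    Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates annual neonatal, infant, and under-five mortality
    trends from summary birth histories (SBH).  A discrete-time survival
    additive model is trained on complete birth histories (CBH), per-child
    discrete hazards are predicted for the hypothetical children of each
    SBH respondent, and the predictions are aggregated with empirical
    probability-of-birth weights into age-specific population trends with
    simulation-based uncertainty.  Also provides direct CBH hazard
    tabulation, a predictive-validity metric suite, and a synthetic
    birth-history generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
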