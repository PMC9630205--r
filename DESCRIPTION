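Package: bdat
Title: Beat-Drop Alignment Test: Item Bank, Response Models, and Adaptive
    Administration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Psychometric engine for the Beat-Drop Alignment Test (BDAT), a
    one-alternative forced-choice measure of covert musical beat continuation.
    Builds the calibrated item bank (probe displacement levels spaced equally
    on a perceptual-accuracy scale, full combinatorial item variants, exact
    probe timing on the beat grid), renders schematic audio stimuli with
    sample-accurate onsets, implements the explanatory item-response models
    for on-beat and off-beat probes (mixed-effects logistic regression with
    modified asymptotes, equivalent to a constrained four-parameter logistic
    IRT model), fits those models to response data with crossed participant
    and track random intercepts, administers the computerized adaptive test
    with expected-a-posteriori ability estimation, and validates the whole
    pipeline by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
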