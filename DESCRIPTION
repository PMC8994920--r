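Package: mobproj
Title: Sequential Multiple-Imputation Projections of Mobility Limitations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the prevalence of mobility limitations (difficulty
    climbing stairs, difficulty walking across a room) in ageing cohorts by
    sequential multiple imputation. Harmonised multi-study longitudinal survey
    panels are completed with chained equations whose conditional models are
    classification and regression trees with donor draws; projections advance a
    sliding multi-wave window two calendar years at a time, imputing each new
    wave from the trailing waves under a transition-stationarity assumption.
    Sampling uncertainty is propagated by a Rao-Wu rescaled bootstrap, and
    physical-activity intervention scenarios are incorporated as a normal shift
    of disability sum scores scaled by a meta-analytic standardised mean
    difference. Includes a synthetic cohort generator with closed-form
    prevalence oracles so every stage of the pipeline is testable without
    access-controlled survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
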