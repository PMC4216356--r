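Package: edemascore
Title: Standardized Scoring and Reader-Study Evaluation of Pulmonary Edema
    on Bedside Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a weighted ordinal scoring rubric for the
    radiographic assessment of pulmonary edema on bedside (supine,
    antero-posterior) chest radiographs: nine characteristic indicators
    are graded on three- or four-point severity scales, weighted points
    are summed, and totals above a decision threshold classify the
    radiograph as showing pulmonary edema.  Alongside the rubric the
    package provides the evaluation machinery for paired multi-reader
    diagnostic-accuracy studies against an extravascular lung water
    (EVLW) reference standard: pooled and per-reader sensitivity,
    specificity and predictive values with exact (Clopper-Pearson) or
    Wilson confidence intervals, mean pairwise inter-reader agreement,
    free-marginal multirater kappa, and the net reclassification index
    for paired binary classifiers.  A synthetic reader-study generator
    simulates EVLW cohorts, latent indicator severities and noisy
    readers so the whole pipeline can be exercised end-to-end without
    any radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
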