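Package: mpoutcomes
Title: Abnormal-Point Microperimetry Outcomes for Clinical Trials in
    Intermediate AMD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs clinical-trial outcome measures from mesopic
    microperimetry exams of eyes with intermediate age-related macular
    degeneration. Scores pointwise deviations of threshold sensitivity
    against an age-linear normative model, applies a cohort-based device
    calibration offset, classifies grid points as abnormal at the 5% and
    2.5% normative tails, summarises abnormal-point endpoints per eye and
    per cohort, screens eyes for trial eligibility by minimum abnormal-point
    count, and quantifies test-retest repeatability with Bland-Altman 95%
    limits of agreement and separation from healthy eyes with Cohen's d.
    Includes a synthetic-cohort generator with a focal-lesion model so the
    whole pipeline is testable without patient data, plus CSV input/output
    and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
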