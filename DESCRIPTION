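Package: wearrehab
Title: Continuous Wearable Activity and Heart Rate Monitoring Analysis for
    Inpatient Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 48-hour chest-worn wearable recordings in
    inpatient rehabilitation: computes the moving standard deviation of
    tri-axial acceleration (MSDA) as a step-count-free measure of physical
    activity, classifies posture (lying, sitting or standing, walking) from the
    gravity vector and gait cadence, derives exercise intensity as percent
    heart rate reserve anchored to a night-time resting heart rate, splits each
    day into therapist-scheduled training and nontraining periods, and runs the
    paired cohort statistics (exact Wilcoxon signed-rank tests and Spearman
    rank correlations against functional scores and age). A fully annotated
    synthetic-cohort generator emulates the ward recording protocol so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
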