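Package: d50fit
Title: Logistic D50 Modelling of ALS Functional Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the sigmoidal logistic decay model of revised ALS
    Functional Rating Scale (ALSFRS-R) trajectories, in which D50 is the
    time since symptom onset at which a patient reaches half the maximal
    score of 48 and dx is the curve's steepness denominator. Provides
    trajectory ingestion and validation for long-format clinic-visit data,
    conventional-slope initialisation, per-patient bounded nonlinear
    least-squares fitting with case-resampling bootstrap confidence
    intervals, explicit degenerate-fit detection for slow progressors,
    slow/fast progressor classification, cohort-level descriptive
    summaries, observed-versus-predicted agreement statistics, and a
    synthetic-cohort simulator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
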