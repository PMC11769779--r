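Package: autopesi
Title: Automated Pulmonary Embolism Severity Index Scoring and Agreement Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the Pulmonary Embolism Severity Index (PESI) automatically
    from structured emergency-department encounter snapshots, the way an
    EHR-embedded calculator does at the moment a CT pulmonary angiogram is
    ordered: comorbidities are flagged by hierarchical SNOMED CT concept
    matching over the problem list and past medical history, vital-sign
    criteria use the most adverse value charted before the trigger instant,
    and oxygenation and mental-status criteria follow explicit clinical rules.
    Includes a synthetic paired-cohort simulator with realistic
    documentation-error processes (omitted problem-list entries, late-charted
    vitals, sex conflation), a deterministic study-replica fixture, and the
    full agreement-validation toolkit used to benchmark an automated score
    against blinded physician chart review: exact binomial confidence
    intervals, Cohen's kappa, logistic-regression odds ratios, Bland-Altman
    limits of agreement, and per-component error tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
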