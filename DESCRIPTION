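Package: adtriage
Title: Two-Cutoff Triage Evaluation for Alzheimer's Blood Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating blood-based biomarkers of Alzheimer's
    disease pathology under single- and two-cutoff (triage) classification
    rules. Provides bootstrap-based derivation of cutoffs at fixed
    specificity or sensitivity and at the Youden point, tri-level
    classification with an intermediate (gray) zone, accuracy/PPV/NPV/AUC
    estimation with percentile bootstrap confidence intervals under the
    intermediate-exclusion rule, DeLong and bootstrap hypothesis tests for
    comparing markers and subgroups, Gaussian-mixture derivation of a CSF
    reference-standard cutoff, a cost model for blood-test-first triage
    strategies, and a calibrated synthetic cohort generator so the whole
    workflow can be exercised end to end without access to restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
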