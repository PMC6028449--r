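Package: cdepa
Title: Rule-Based Screening for Advanced Parkinson's Disease and
    Diagnostic-Validation Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CDEPA screening questionnaire for advanced
    Parkinson's disease as an editable rule map plus a deterministic
    certainty-level engine (definitive/probable/possible symptom tiers with
    combination promotions), scores the companion clinical rating scales
    (Hoehn-Yahr staging, SCOPA-Motor, Non-Motor Symptoms Scale, CISI-PD,
    clinician and patient global impressions) and binarizes the five-level
    clinical-judgment gold standard.  Provides the complete screening-test
    validation toolkit: 2x2 diagnostic performance (sensitivity, specificity,
    predictive values, accuracy, binary-classifier AUC), Cohen's kappa with
    Landis-Koch interpretation, percent agreement, Spearman correlation,
    Mann-Whitney U with an exact-enumeration small-sample path,
    Kruskal-Wallis, Fisher's exact test, Youden-index cutoff finding and
    one-sample proportion power.  A seeded synthetic-cohort generator with a
    latent-severity model reproduces the statistical structure such a
    validation study assumes, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
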