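Package: ptbpanel
Title: Serum Biomarker Panel Analysis for Spontaneous Preterm Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for validating a three-protein
    serum biomarker panel (GPX3, NID1, PAPPA2) that predicts spontaneous
    preterm birth. Implements multi-study placental differential-expression
    meta-analysis by robust rank aggregation with DerSimonian-Laird
    random-effects pooling and Fisher's combined probability; peptide-level
    quality control, normalization and protein roll-up for targeted
    proteomics; gestational-age-specific multiples-of-median adjustment
    with within-cohort z-scoring; composite risk scoring with Youden
    threshold transfer across cohorts; ROC/bootstrap performance
    evaluation with prevalence-weighted predictive values; and
    Kaplan-Meier time-to-delivery comparison of predicted risk groups.
    Includes a synthetic-cohort generator emulating a four-site nested
    case-control design so every stage is testable without access to the
    original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC
Config/testthat/edition: 3
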