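Package: seromir
Title: Validation of Serum microRNA Biomarkers for NAFLD Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating circulating microRNA biomarkers of
    nonalcoholic fatty liver disease (NAFLD) severity from raw qPCR
    threshold cycles and clinical/histology records. Implements Ct-level
    detection quality control, geNorm reference-gene stability ranking,
    geometric-mean reference normalization with 2^-ddCt relative
    quantification, histological severity scores (NAS, SAF activity,
    fibrosis staging) and serum fibrosis algorithms (FIB-4, APRI, BARD,
    NAFLD fibrosis score, HOMA-IR), adaptive two-group testing,
    ratio-biomarker construction with empirical ROC / Youden cut-off
    analysis and full diagnostic metric panels with confidence intervals,
    and PLS-DA classification (NIPALS) with leave-one-out cross-validation
    over clinical, miRNA and combined variable panels. A synthetic cohort
    generator reproduces the three-group NAFLD study structure plus a
    drug-induced liver injury comparator so the whole pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    pROC
Config/testthat/edition: 3
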