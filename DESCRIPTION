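Package: fpmdst
Title: Ex Vivo Drug Sensitivity Testing and Functional Precision Medicine
    Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for functional precision medicine (FPM)
    drug sensitivity testing (DST) of patient-derived tumor cells: 384-well
    luminescence plate ingestion, Z-prime plate quality control, control-based
    normalization, four-parameter log-logistic dose-response fitting with IC50
    extraction, drug sensitivity scores (DSS, normalized area above an activity
    threshold), Cmax-gated therapy ranking and tumor-board reporting, and the
    clinical-outcome statistics used in FPM feasibility studies: exact binomial
    primary-endpoint testing with Clopper-Pearson intervals, Barnard's
    unconditional exact test, exact paired Wilcoxon, logrank, Mann-Whitney,
    Spearman correlation and ROC-based DSS cutoff analysis. Includes seeded
    synthetic-data generators for plates, screens and clinical cohorts so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
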