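Package: pmesig
Title: Proteomic Signatures and Subtyping of the Peritumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free proteomic characterization of the
    peritumor microenvironment (PME) in hepatocellular carcinoma. From a
    protein-abundance matrix (iBAQ-like intensities) and a clinical table it
    derives differentially expressed proteins, occurrence (PME-O) and
    progression (PME-P) marker signatures selected by ROC and log-rank
    screening, per-patient functional-category risk indices, three-marker
    logistic occurrence and Cox prognostic models, and non-negative matrix
    factorization (NMF) consensus subtypes. Includes a self-contained
    statistical kernel (ROC/AUC, Kaplan-Meier, log-rank, Cox proportional
    hazards, logistic regression, exact and asymptotic contingency tests,
    rank correlations) and a synthetic-cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    mclust,
    withr
Config/testthat/edition: 3
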