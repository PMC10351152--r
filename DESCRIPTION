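Package: LiverMetSig
Title: Colon-to-Liver Metastasis Expression Signatures, Drug Repurposing
    and Organoid Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for characterizing colorectal-cancer
    liver metastases from bulk RNA-seq count data: negative-binomial
    differential expression with TMM-style normalization and
    Benjamini-Hochberg correction, derivation of a hybrid
    colon-to-liver metastasis gene signature by intersecting matched,
    unmatched and external cohort contrasts with tissue-enrichment
    classification, pathway-level K-means clustering with gap-statistic
    K selection and replica-based stability assessment, a connectivity-map
    style screen that scores compound perturbation profiles against the
    signature with a weighted Kolmogorov-Smirnov enrichment statistic,
    and patient-derived organoid pharmacology (response score and Bliss
    independence synergy). A synthetic-data module generates cohorts,
    perturbation references and organoid dose grids with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
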