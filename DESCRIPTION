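Package: ipass
Title: Immune Paediatric Signature Score for T-Cell Infiltration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derivation, scoring and evaluation of a T-cell-infiltration
    gene-expression signature for high-risk paediatric tumours. Implements
    the Immune Paediatric Signature Score (IPASS): a 15-gene mean
    log2(TPM + 1) score, min-max normalised to [-1, 1] and thresholded to
    classify tumours as T-cell infiltrated or immune cold. Includes
    signature derivation from IHC-labelled cohorts via random-forest Gini
    importance, diagnostic-classification metrics, the accompanying
    statistical decision flow, and ancillary tumour-immune biomarker rules
    (neoantigen IC50 filtering, PD-L1 IHC/RNA concordance, immune-archetype
    assignment, TCR clonotype summaries), together with a seeded synthetic
    cohort generator so every stage is testable without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
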