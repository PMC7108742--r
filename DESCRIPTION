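Package: markerpipe
Title: Standardized Biomarker Screening for Quantitative Omics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end screening of quantitative omics matrices (microarray,
    RNA-seq counts, mass-spectrometry abundances) for candidate biomarkers.
    Covers missing-value imputation (local least squares and k-nearest
    neighbours), count filtering, TMM scale factors and voom precision
    weights, quantile/mean/median normalization, distributional diagnostics
    (Cullen-Frey bootstrap clouds, maximum-likelihood fits), k-means
    clustering with BIC model selection and classical MDS, moderated-t
    differential expression with empirical-Bayes variance shrinkage,
    elastic-net variable selection with repeated cross-validation and AUC,
    weighted co-expression modules via topological overlap, per-variable Cox
    proportional-hazards screening with assumption checks, and integration of
    protein-protein and miRNA-gene interaction tables. Includes a synthetic
    data generator so every stage is testable without external downloads, and
    a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    glmnet,
    survival,
    jsonlite,
    withr,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
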