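Package: radsig
Title: Network-Based Radiomic Signature Extraction and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for binary tumor classification from wide radiomic
    feature tables and categorical clinical variables. Implements parsing of
    the pyRadiomics feature-naming dialect into category metadata
    (modality, filter class, feature family), z-score and median/IQR robust
    standardization, bias-corrected Cramer's V association screening,
    an unsupervised batch-effect audit (2-D embedding, density-based
    hierarchical clustering, pairwise Fisher exact cluster enrichment), the
    DNetPRO network-based feature-signature extraction algorithm (exhaustive
    feature-couple scoring with a linear support vector machine, top-couple
    graph construction, connected-component candidate signatures, penalized
    logistic signature evaluation, selection procedures A and B), and a
    Matthews-correlation repeated stratified cross-validation benchmark
    harness with Wilcoxon comparisons. Ships a synthetic cohort generator
    that emulates the multi-center sinonasal-tumor study design the pipeline
    was built for, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
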