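Package: spfmProfiles
Title: Sparse Poisson Factorization Profiling of Mental Well-Being
    Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end digital-phenotyping analysis of short self-reported
    mental well-being questionnaires. Raw 0-100 item scores are
    valence-inverted and dichotomized at each item's top decile to isolate
    extreme responders; the resulting binary response matrix is decomposed
    by a Sparse Poisson Factorization Model - an Indian Buffet Process
    latent feature model with an always-active bias term and nonnegative
    item weights - fitted by Gibbs sampling with Poisson data augmentation.
    Patients are clustered on the latent activation matrix with K-means
    into symptom profiles, and profiles are linked to clinical records
    (ICD-10 diagnostic chapters, Clinical Global Impression scores, age,
    sex) through contingency tables and homogeneity tests. A seeded
    synthetic cohort generator with planted latent structure supports
    testing and calibration of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
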