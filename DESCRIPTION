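Package: chemoprofiler
Title: Chemogenomics Profiling of Compound-Target Bioactivity Space
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale chemogenomics toolkit for navigating
    compound-target bioactivity space. Standardizes heterogeneous
    bioactivity measurements (IC50, Ki, pKi and related types) into
    per-target z-scores oriented so that larger means stronger binding;
    decomposes compound libraries into hierarchical ring-scaffold trees;
    runs Tanimoto fingerprint similarity searches over path-based and
    circular (Morgan) 1024-bit fingerprints; predicts targets for compound
    sets with a Similarity Ensemble Approach calibrated against random set
    pairs and scored with an extreme-value tail; trains per-target ensembles
    of fifteen Bernoulli naive Bayes QSAR classifiers weighted by
    cross-validated performance; maps protein interaction neighborhoods to
    annotation terms with corrected hypergeometric enrichment; and
    assembles pharmacological heatmap matrices ordered by scaffold tree and
    protein family, with optional gap-filling from the predictors. A seeded
    synthetic-data generator provides compound libraries, activity tables,
    interaction networks and annotation sets with planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
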