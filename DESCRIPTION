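Package: glycodiff
Title: Differential Expression Analysis of Glycomics Data with
    Motif-Level Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical workflows for comparative glycomics. Glycan
    structures in IUPAC-condensed notation are parsed into rooted
    labeled trees, annotated with named, terminal and exhaustive
    substructure motifs via wildcard-aware subtree matching, and
    converted into proportional motif abundances. Robust preprocessing
    covers sparsity filtering, total-abundance normalization, iterative
    random-forest imputation of missing values and variance-stabilizing
    normalization. Differential expression between two groups (Welch or
    paired t-tests, Cohen's d/d_z, Hotelling's T2 and Mahalanobis
    distance for correlation-network motif sets, Levene's test,
    Benjamini-Hochberg correction), multi-group ANOVA with Tukey HSD,
    time-series regression, and fixed- or random-effects
    (DerSimonian-Laird) meta-analysis are provided, together with a
    Dirichlet simulator of compositional glycomics experiments with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    igraph,
    ranger,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    metafor,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
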