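Package: ppibench
Title: Benchmarking Network-Based Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for benchmarking network-based link prediction on
    protein-protein interaction (PPI) networks. Implements classical and
    L3-family similarity indices, stochastic block model link reliability,
    factorization and diffusion scorers, a standardized 10-fold
    cross-validation harness with imbalance-aware ranking metrics and
    combined z-scores, the structural consistency index of network
    predictability, stacking and rank-aggregation consensus models,
    prediction-pattern analytics, and seeded generators of synthetic
    PPI-like interactomes (duplication-mutation-complementation growth,
    Erdos-Renyi controls, degree-preserving rewiring, planted blocks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    MASS,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
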