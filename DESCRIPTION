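Package: fusenet
Title: Multi-Source Gene Regulatory Network Inference with Fused Ridge Regression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous estimation of transcription-factor to gene
    regulatory networks from several expression data sources (species,
    strains, or platforms) by multi-output ridge regression with pairwise
    L2 fusion penalties on a-priori analogous interactions (orthology,
    operon membership). Includes a direct augmented-matrix solver that
    decomposes the joint problem into independently solvable constraint
    components, an iterative path solver, a non-convex saturating
    ("adaptive") fusion penalty optimized by local quadratic approximation
    that learns which constraints to relax, transcription-factor activity
    estimation from prior networks, confidence scoring and
    precision-recall evaluation against gold standards, two-stage
    cross-validated hyperparameter selection, and a synthetic-data
    generator emulating paired regulatory networks with corruptible
    orthology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
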