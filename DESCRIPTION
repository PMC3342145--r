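Package: gfmap
Title: Structured Association Mapping with the Graph-Guided Fused Lasso
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for structured association mapping of
    genomic markers to correlated quantitative traits. Builds trait
    correlation networks, prescreens markers with cross-validated lasso
    regression, decomposes the trait network into bounded sub-networks via
    connected components and spectral clustering, and fits the graph-guided
    fused lasso (GFlasso) by smoothing proximal-gradient optimization with a
    three-stage cross-validated search over the sparsity and fusion
    regularization parameters. The fourteen analysis steps are orchestrated
    as a checkpointed, resumable pipeline over a file-backed workspace.
    Includes single-marker Wald and Wilcoxon rank-sum baselines and a
    seeded simulator of modular trait data with known sparse, fused marker
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    parallel,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'network.R'
    'screen.R'
    'gflasso.R'
    'gfmap-package.R'
    'pipeline.R'
    'simulate.R'
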