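Package: circuitflow
Title: Influence Propagation and Module Discovery in Synapse-Count Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing directed synapse-count connectomes of a
    central nervous system. Builds input-fraction-normalised connectivity
    matrices rescaled for stable linear dynamics, computes steady-state
    "influence" scores from seed cells to target cells (with pooled, batched
    and adjusted log-scale forms), provides probabilistic graph-traversal
    baselines (signal cascade and information flow), clusters effector and
    ascending/descending cells into behaviour-centric modules via cosine
    similarity, UMAP embedding, Ward linkage and an adaptive dendrogram cut,
    partitions the CNS graph into networks by spectral clustering, and
    computes per-cell statistics (laterality, axon/dendrite segregation,
    region output fractions). A synthetic-connectome generator with planted
    ground truth (body-part sensorimotor loops, layered feedforward chains,
    planted partitions) makes the full pipeline testable without any data
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RSpectra,
    dplyr,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    uwot,
    withr
Suggests:
    deSolve,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
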