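Package: connalign
Title: Weighted Graph Jaccard Similarity and Weisfeiler-Leman Alignment
    of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing and aligning weighted undirected brain
    networks (structural connectomes). Implements the weighted graph
    Jaccard index (a Ruzicka-type similarity whose complement is a metric
    on the space of connectomes), classical norm-based and cosine
    similarities, and WL-align, a Weisfeiler-Leman-inspired node-signature
    algorithm that recovers node correspondences between two connectomes
    via minimum-cost bipartite assignment. Includes preprocessing rules
    for streamline-count connectomes (negative thresholding, isolated-node
    repair, weight normalisation, hemisphere splitting), synthetic
    connectome generators with ground-truth permutations for validation,
    and an evaluation harness computing node matching ratios and
    similarity-based alignment quality metrics over cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
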