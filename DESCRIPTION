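Package: mol3dkern
Title: 3D Graph Kernels for Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes positive semidefinite similarity kernels between small
    molecules that incorporate 3D structural information: bond lengths, bond
    angles and torsion angles, all derived from pairwise inter-atomic
    distances so that every kernel is invariant to rigid motions of the
    conformer. Implements the 3D chain-motif graph kernel (a GraphHopper
    kernel over a graph whose nodes are 4-atom chain motifs), an efficient 3D
    GraphHopper kernel with a 3-hop neighborhood node kernel, the 2D
    GraphHopper baseline and a 2-hop ablation variant. Includes an SDF (MOL
    V2000) front end, synthetic 3D molecule generators for testing, Gram
    matrix assembly with optional cosine normalization, and a virtual
    screening harness (balanced subsampling, stratified 70/15/15 splits,
    precomputed-kernel SVM with C grid search, Wilcoxon signed-rank kernel
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    kernlab,
    withr,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
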