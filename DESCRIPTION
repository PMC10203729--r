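Package: germmap
Title: Label Transfer, Spatial Projection and Optimal-Transport Lineage
    Reconstruction for Single-Cell Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping in vitro single-cell transcriptomes onto in
    vivo references and for reconstructing lineage relationships across a
    differentiation time course. Implements k-nearest-neighbour label
    transfer with per-cell hypergeometric enrichment tests, projection of
    dissociated cells onto a spatially resolved 3D reference via shared
    nearest-neighbour weighted averaging with group density maps,
    adaptive-kernel diffusion maps with diffusion pseudotime, and
    Waddington-style lineage reconstruction from unbalanced entropic
    optimal-transport couplings (cluster contribution matrices, power
    thresholding, directed KNN lineage graphs and random-walk
    meta-clusters). A negative-binomial generator of branching time
    courses with planted ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
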