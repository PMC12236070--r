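Package: pathcell
Title: Pathway-Level Analysis, Scoring and Annotation for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for pathway-centric analysis of single-cell
    RNA-seq matrices. Provides ontology-aware gene-set management (GMT, minimal
    OBO and GAF readers, hierarchy pruning and subtree/end-level filtering),
    per-cell AUCell recovery-curve enrichment scoring, clustering and embedding
    of cells in pathway-score space, semi-automated cluster annotation from
    marker signatures, group-level statistics (z-scores, log fold changes,
    proportion positive, Broad-style running enrichment scores with
    Kolmogorov-Smirnov tests), professional categorical palette generation with
    RGB and RYB multi-feature color blending, offline gene-identifier and
    cross-species matrix conversion, and a negative-binomial simulator that
    plants cell types, pathway programs and batch effects so every component is
    testable without external downloads. Includes a 'pathcell' command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    farver,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    uwot,
    yaml
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
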