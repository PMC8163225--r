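Package: netpca
Title: Network Principal Component Analysis and Metabolic Network
    Contextualization for Multi-Block Metabolomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits network principal component analysis (NetPCA) models to
    collections of data matrices linked by shared observation groups and
    shared variable blocks, as arise in multi-cohort, multi-assay LC-MS
    metabolomics. Components are extracted by constrained alternating least
    squares with common scores per observation set and common loadings per
    variable block, with block-influence and per-metabolite explained
    variance decompositions for marker selection. Companion tools cover
    QC-based feature filtering and LOESS signal-drift normalization,
    pathway over-representation analysis with Benjamini-Hochberg
    correction, compound-graph operations on metabolic networks
    (compartment collapse, side-compound exclusion, carbon-transfer
    filtering, squared-degree lightest paths), and complete-linkage
    clustering of reaction-path distances into metabolic modules.
    Synthetic-data generators emulating a chronic kidney disease cohort
    design and toy pathway-annotated networks make the full workflow
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    cluster,
    jsonlite
Config/testthat/edition: 3
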