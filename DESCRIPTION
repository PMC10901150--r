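Package: toxmodnet
Title: Co-Expression Module Networks for Toxicogenomic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for network-based analysis of
    toxicogenomic dose-time-response transcriptomics, as used to study
    drug-induced liver injury in hepatocyte models. Covers sample quality
    control and CPM normalisation of targeted RNA-seq counts, log2
    fold-change computation against matched vehicle controls, unsigned
    weighted gene co-expression network construction with topological
    overlap clustering, module eigengene scoring and merging,
    permutation-based module preservation statistics (Zsummary, median
    rank), module-versus-cell-death correlation screening with multi-part
    hit criteria, candidate gene selection, and z-score scoring of RNA
    interference cell-death screens. A synthetic-data generator with
    planted co-expression modules, planted preservation structure,
    module-coupled cell-death traits and planted siRNA effects makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
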