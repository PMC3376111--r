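Package: graftnet
Title: Temporal Differential Expression and Backpropagation Interaction
    Networks for Cell-Specific Transcriptomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for temporal, cell-type-resolved bulk
    transcriptome studies of vascular injury. Provides empirical-Bayes
    moderated per-timepoint differential expression, a moderated
    F-statistic for time-course gene selection, K-means clustering of
    temporal fold-change profiles, hypergeometric gene-set
    over-representation, construction of layered gene-interaction
    networks by backpropagation from the final timepoint, dominant
    pathway selection, and DMNC (density of maximum neighborhood
    component) hub scoring with cross-cell-type signature-network
    extraction. Includes a synthetic-data generator with planted
    differential expression, planted network hubs, and planted dominant
    gene sets so that every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
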