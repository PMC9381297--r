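Package: diseasomeR
Title: Cross-Comparative Differential Expression and Diseasome Network
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Links a focal disease to candidate risk factors through a
    reproducible cross-comparative pipeline: per-cohort differential
    expression calling (unpaired Student's t-test, log2 fold-change
    thresholds, Benjamini-Hochberg false discovery rate), directional
    overlap of differentially expressed genes, Jaccard-scored gene-disease
    bipartite ("diseasome") network construction, degree-based hub-protein
    ranking on a protein-protein interaction network, and local
    hypergeometric over-representation analysis against GMT gene-set
    libraries.  A synthetic multi-cohort generator with planted ground
    truth provides a test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
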