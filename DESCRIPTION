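Package: cernascope
Title: CircRNA-miRNA-mRNA Regulatory Network Analysis with Concordant
    Dysregulation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for competing-endogenous-RNA (ceRNA) analysis of two-group
    expression studies across three RNA layers (circRNA, miRNA, mRNA):
    quantile normalization, exact Mann-Whitney differential-expression calling
    at small sample sizes with fold-change thresholds, composition of
    circRNA->miRNA and miRNA->mRNA target maps, construction of
    direction-concordant circRNA-miRNA-mRNA regulatory triples, odds-ratio and
    miRNA-adjusted logistic statistics for concordant dysregulation,
    hypergeometric gene-set enrichment of network mRNAs, Cytoscape-ready
    network export, and a synthetic-data generator with planted sponge effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
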