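Package: abkey
Title: Key Gene Module Discovery for Phenotype Gene Sets in Case-Control Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis that narrows a broad phenotype gene set
    (such as the mouse "abnormal behavior" set) to key disease risk-gene
    modules per brain region and gene-evidence type. Provides negative-binomial
    differential expression with median-of-ratios normalization, weighted
    co-expression network construction (soft-thresholded adjacency, topological
    overlap, hierarchical module detection and eigengene-based merging),
    odds-ratio/chi-square key-module selection, hypergeometric over-representation
    analysis over gene-set collections, expression-weighted specificity bootstrap
    enrichment across cell types or developmental periods, a degree bootstrap
    test on brain-expressed protein-protein interaction networks, and a
    synthetic-data generator with planted structure so the whole pipeline is
    testable without external downloads.
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
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
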