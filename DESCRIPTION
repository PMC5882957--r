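Package: bridgenet
Title: Multi-Tissue Gene Co-Expression Networks, PCIT Edge Selection and
    Bridging-Gene Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds gene co-expression networks from multi-tissue
    time-course expression data using the PCIT (partial correlation and
    information theory) algorithm, partitions them into tissue-specific
    sub-networks, identifies bridging genes connecting tissues and rebuilds
    the core network they form. Includes stringent differential-expression
    filtering for network input selection, expression-profile clustering
    (k-means with median centring, PAM), sample PCA, condition-correlation
    matrices, hypergeometric gene-set enrichment with Benjamini-Hochberg
    correction, qPCR relative quantification (2^-ddCT) and cross-platform
    concordance statistics. A synthetic-data generator plants tissue-specific
    temporal co-expression modules and bridging genes with known ground
    truth so that every stage of the pipeline can be validated offline.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
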