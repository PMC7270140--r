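Package: menimm
Title: Location-Resolved Immune Microenvironment Analysis of Meningioma
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links meningioma anatomical location (skull base versus
    convexity) to the tumour immune microenvironment from bulk expression
    data. Provides multi-study preprocessing (quantile normalisation,
    log2 transform, cross-study merging, empirical-Bayes batch
    correction), weighted gene co-expression network analysis with
    topological overlap and module eigengenes, reference-based immune
    cell deconvolution (non-negative least squares and nu-support-vector
    regression engines), a bipartite cell-cytokine correlation network
    with a per-cell connectivity statistic and unweighted eigenvector
    centrality, hypergeometric over-representation testing against GMT
    gene sets, and a synthetic multi-study cohort generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    limma,
    pracma,
    purrr,
    rlang,
    stats,
    sva,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
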