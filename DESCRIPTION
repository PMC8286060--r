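Package: tripletnet
Title: Modulator-TF-Target Regulatory Triplet Inference and Hierarchical
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers post-translational regulatory triplets (modulator,
    transcription factor, target) from gene expression cohorts using a
    conditional mutual information difference statistic, validates motifs
    across independent cohorts for consistency, and analyses the resulting
    three-layer hierarchical regulatory network: topology with Monte-Carlo
    significance, regulatory loops, binary regulation profiles with
    hierarchical clustering, function-specific subnetworks, and
    hypergeometric over-representation analysis. Includes a multi-cohort
    synthetic expression generator that plants modulator-gated TF-target
    dependencies so the whole pipeline can be benchmarked against known
    truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
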