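Package: mlnpaths
Title: Multilayer Network Path Analysis for Multimodal Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multilayer association networks from subjects-by-variables
    cohort tables with mixed variable types and missing data: binned mutual
    information and Pearson correlation on pairwise-complete observations,
    permutation-test edge significance, per-layer and bipartite connectance,
    signed (activating/inhibitory) correlation networks, synchronous Boolean
    dynamics under noisy square-wave forcing, lagged cross-correlation path
    scoring with k-lowest-score path extraction, and degree-preserving
    network permutation negative controls. Includes a latent-factor synthetic
    cohort generator with planted correlation blocks and cross-layer
    dependency chains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
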