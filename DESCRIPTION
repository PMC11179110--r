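Package: gconnect
Title: General Cognitive Factor Extraction and Functional Connectome Graph Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a general cognitive ability factor (Spearman's g)
    and its relation to group membership and brain-network organization.
    Extracts g from a multi-test neuropsychological battery by exploratory
    factor analysis (sampling-adequacy diagnostics, Velicer minimum-average-partial
    factor-count selection, minimum-residual estimation, gradient-projection
    oblique rotation, Thurstone regression scores), compares groups with pooled
    effect sizes, permutation tests and a two-class Fisher discriminant, and
    analyses resting-state functional connectomes with minimum-spanning-tree
    backbone proportional thresholding, normalized global graph metrics,
    Louvain modularity and the participation coefficient, including
    degree-preserving null models and FDR-corrected group statistics. A
    synthetic-data generator with planted latent structure makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
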