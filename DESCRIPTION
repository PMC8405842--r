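Package: ssgmnet
Title: Single-Subject Gray-Matter Networks and Longitudinal Topology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts single-subject gray-matter networks (SSGMNets) from
    gray-matter density volumes by parcellating the volume into 3x3x3-voxel
    cube nodes, computing rotation- and reflection-maximized Pearson
    similarity between cubes, and binarizing with an individualized
    permutation-null threshold under false-discovery-rate control. Computes
    global and nodal graph-topological attributes (clustering, characteristic
    path length, global efficiency, global connectivity, sparsity) with
    normalization against degree-preserving randomized reference networks and
    the small-world coefficient, plus regional aggregation over an atlas.
    Provides two-visit rate-of-change analysis and the accompanying
    statistical battery: ANCOVA with type-III sums of squares and omega-squared
    effect sizes, normality-gated transformations, Levene tests, post hoc
    comparisons, Benjamini-Hochberg correction, partial correlations,
    Fisher-z comparison of correlations, and ICC(2,1) test-retest
    reliability. Includes a synthetic-data generator producing smooth
    gray-matter-like volumes, blocky atlases, and two-visit cohorts with
    injected group and longitudinal effects so the full pipeline can be
    exercised end-to-end without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    igraph,
    RNifti,
    car,
    nortest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
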