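Package: popmodes
Title: Population Activity Modes and Coding Geometry for Delayed-Response Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-aligned extracellular recordings from
    frontal cortex during delayed-response decision tasks. Builds
    peri-stimulus time histogram (PSTH) response matrices, embeds and clusters
    response profiles (t-SNE plus density-peak clustering), tests coding-vector
    clouds for nonuniform mixing (ePAIRS), decomposes population activity into
    seven orthogonalized activity modes (stimulus, choice, action, outcome,
    ramping, go, response), quantifies coding geometry and functional
    populations, decodes task variables from pseudo-populations, measures
    pairwise noise correlations, and provides perturbation and connectivity
    statistics (nested bootstrap for photoinhibition behavior, optogenetic
    tagging, EPSP feature extraction). Includes a synthetic-session generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Rtsne,
    cluster,
    e1071,
    igraph,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
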