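Package: KinomeQSAR
Title: Kinase Selectivity Profiling with Descriptor-Based Neural Network
    QSAR Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative structure-activity relationship (QSAR) modelling
    of kinase inhibitor selectivity profiles. Encodes small molecules as
    fixed-length translation- and rotation-invariant descriptor vectors
    (scalar 1D/2D counts, topological autocorrelations, radial distribution
    functions and 3D autocorrelations over atomic properties such as PEOE
    partial charge, electronegativity and polarizability), binarizes
    compound x kinase Kd activity matrices at configurable cutoffs, trains
    a multi-task feed-forward neural network (one sigmoid output per
    kinase) by online back-propagation with momentum, and evaluates
    predictions with confusion metrics including the Matthews correlation
    coefficient, per-kinase ROC/AUC distributions, per-kinase decision
    thresholds, paired rank tests and Fisher comparisons against a random
    caller. Includes a synthetic planted-signal panel generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph,
    ChemmineOB,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
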