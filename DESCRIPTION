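Package: intentnet
Title: Suicidal Intent Networks and Deep Lethality Prediction
Version: 0.1.0
Authors@R: person("Analytics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing antecedent behaviours of suicide attempts
    measured by the 15-item Beck Suicide Intent Scale (SIS). Provides a
    seeded synthetic-cohort generator with planted group-specific partial
    correlation structure, pairwise relationship signatures (interaction,
    harmonic mean, tangent of angle difference) over all SIS item pairs,
    graphical-lasso intent networks with permutation-tested edges and
    topology summaries, a small convolutional classifier (E-GONet) of
    attempt medical lethality with linear-regression and random-forest
    baselines, stratified cross-validation with precision-recall-gain
    metrics, and Gradient*Input saliency maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    xml2,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
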