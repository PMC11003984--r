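Package: coregrn
Title: Data-Driven Inference, Optimization and Perturbation Modeling of
    Core Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs context-specific core gene regulatory networks
    (GRNs) of transcription factors by combining ranked TF lists, a
    curated TF-target database merged with chromatin-accessibility
    derived targets, and TF activity correlations; simulates each
    candidate network with an ensemble of ordinary differential
    equation models using shifted-Hill kinetics and randomly sampled
    kinetic parameters; selects the optimal network by a combined
    accuracy and flexibility ranking; and screens in-silico single and
    double gene knockdowns for regulators that destabilize the
    observed expression states.  Includes a synthetic-data generator
    planting a bistable two-module GRN so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
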