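Package: devmass
Title: Deviance Detection with Reciprocally Coupled Neural-Mass Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Networks of reciprocally coupled excitatory/inhibitory
    neural-mass nodes acting as local change detectors. Provides the
    single-population synaptic-kernel and sigmoid primitives, a fixed-step
    batched network integrator with synaptic adaptation and
    covariance-driven short-term plasticity, stimulus protocol generators,
    simulated MEG observables, a nine-way On/Off response categorizer,
    grid scans of inter-node connectivity under pharmacological and
    plasticity conditions, and end-to-end simulation experiments for
    cortical On/Off responses, onset/offset receptive fields, the
    omitted-stimulus response and sequence mismatch negativity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
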