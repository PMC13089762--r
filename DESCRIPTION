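Package: errnet
Title: Error-Neuron Cortical Microcircuit Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of phaseless, multi-compartment
    rate-neuron microcircuits in which separate representation and error
    populations approximate error backpropagation across a loose cortical
    hierarchy. Provides Euler-discretised neuron dynamics with prospective
    (anticipatory) rate coding, an always-on delta-rule plasticity with
    approximate weight transport, noise-driven dendritic reconstruction of
    activation-function derivatives, generators for the benchmark task suite
    (cart-pole distillation from a linear-quadratic regulator, delayed
    match-to-sample, Yin-Yang classification, teacher-student regression and
    class-conditioned image generation), and reference baselines (layered
    networks trained with exact backpropagation and a leaky recurrent network
    trained with backpropagation through time) together with alignment-angle
    and loss metrics.
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
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
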