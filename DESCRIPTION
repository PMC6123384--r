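Package: spikefix
Title: Fixed-Point Event-Driven Spiking Neural Network Simulator with
    Three-Factor Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Behaviourally exact software model of a multiplier-less,
    fixed-point, event-driven spiking neural network fabric. Neurons are
    multi-compartment linear units whose couplings are signed power-of-two
    shift coefficients; synaptic weights are 8-bit with stochastic blank-out
    and randomized rounding; learning is a three-factor, forward-table,
    nearest-neighbour spike-timing rule modulated by a neuron state
    component. Includes builders for Mihalas-Niebur neuron behaviours,
    Amari neural-field bump, selection and tracking dynamics, event-driven
    random back-propagation, an event-based restricted Boltzmann machine
    trained with event-driven contrastive divergence, and a voltage/calcium
    sequence-learning rule, together with deterministic synthetic input
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
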