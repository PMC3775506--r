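Package: mbpnet
Title: Motion-Based Prediction in a Spiking Neural Network on a Retinotopic Torus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a network of conductance-based leaky integrate-and-fire
    neurons arranged on a retinotopic map with toroidal (periodic) topology,
    whose lateral connectivity can be wired at random, isotropically, or
    anisotropically as a function of each neuron's position and velocity
    tuning. A moving-dot stimulus is encoded as an inhomogeneous Poisson
    process and interrupted by blank periods during which the input loses all
    selectivity; a population-vector decoder with circular statistics reads a
    probabilistic estimate of target position and direction back out of the
    spike trains. The package provides the network construction rules
    (distance-dependent Gaussian kernels, motion-based latency wiring, and
    direction-based von Mises wiring), an event-driven spiking simulator with
    synaptic delays, the stimulus generator, the decoder, and an experiment
    driver that compares motion extrapolation performance across connectivity
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
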