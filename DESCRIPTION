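Package: DecisionNet
Title: Spiking Attractor Network for Binary Perceptual Decision-Making
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a two-population cortical attractor
    network for binary perceptual decisions. Leaky integrate-and-fire neurons
    with multi-receptor exponential postsynaptic currents (AMPA, NMDA, GABA and
    an external-noise channel) form two stimulus-selective excitatory
    populations competing through shared feedback inhibition; slow NMDA
    reverberation supports evidence integration and post-stimulus persistent
    activity. The package provides an exact-propagator clock-driven simulator,
    a Poisson motion-coherence stimulus model, decision and reaction-time
    readouts, Weibull neurometric fits, and scripted experiments: coherence
    sweeps, zero-coherence coin-toss trials, stimulus-duration and
    decision-reversal protocols, and mechanism ablations (reduced recurrent
    excitation, fast NMDA).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DecisionNet-package.R'
    'RcppExports.R'
    'stimulus.R'
    'network.R'
    'simulate.R'
    'analysis.R'
    'experiments.R'
    'io.R'
    'simulator.R'
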