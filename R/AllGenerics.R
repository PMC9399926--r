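#' @name DecisionNet-generics
#' @title Generics for DecisionNet classes
#' @description Accessor and action generics shared across the package's
#'   S4 classes.
#' @param x,object an object of the documented class.
#' @param ... further arguments passed to methods.
#' @keywords internal
NULL

#' @rdname DecisionNet-generics
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname DecisionNet-generics
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname DecisionNet-generics
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Build a runnable network from a configuration
#'
#' Instantiates the neurons and the pairwise-Bernoulli connectivity of every
#' projection group in [projectionTable()], computing each group's synaptic
#' current amplitude as `pscAmplitude(target class, port) * J * w * sign`.
#'
#' @param config a [NetworkConfig-class].
#' @param ... passed on to methods; see [buildNetwork,NetworkConfig-method].
#' @return a [DecisionNetwork-class].
#' @export
setGeneric("buildNetwork", function(config, ...) {
  standardGeneric("buildNetwork")
})

#' Simulate one trial
#'
#' Runs the clock-driven simulation of a trial under a [TrialProtocol-class]:
#' background Poisson noise throughout, the coherence-coded stimulus during
#' the stimulus epoch, spikes propagated with per-port delays. The master
#' seed is expanded into four documented substreams (connectivity,
#' background rates, stimulus trace, simulation) so that identical
#' `(configuration, protocol, seed)` triples give identical spike records.
#'
#' @param x a [NetworkConfig-class] (the network is rebuilt from the
#'   connectivity substream, so every trial has its own wiring) or a
#'   pre-built [DecisionNetwork-class] (wiring reused across trials).
#' @param protocol a [TrialProtocol-class].
#' @param seed integer master seed.
#' @param ... passed on to methods.
#' @return a [SpikeTrains-class].
#' @export
setGeneric("runTrial", function(x, protocol, seed, ...) {
  standardGeneric("runTrial")
})

#' Estimate a population's firing-rate trace
#'
#' @param x a [SpikeTrains-class].
#' @param population `"A"`, `"B"` or `"I"`.
#' @param ... passed on to methods; see the method for window, step and
#'   median-filter arguments.
#' @return a [RateTrace-class].
#' @export
setGeneric("populationRate", function(x, population, ...) {
  standardGeneric("populationRate")
})
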