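#' Membrane parameters of one cell class
#'
#' Passive membrane and spiking constants of a leaky integrate-and-fire
#' neuron: resting (leak reversal) potential, spike threshold, post-spike
#' reset, membrane time constant, capacitance and absolute refractory period.
#'
#' @slot vRest resting / leak potential (mV).
#' @slot vTh spike threshold (mV).
#' @slot vReset post-spike reset potential (mV); must lie below `vTh`.
#' @slot tauM membrane time constant (ms), positive.
#' @slot cM membrane capacitance (pF), positive.
#' @slot tRef absolute refractory period (ms), non-negative.
#'
#' @seealso [neuronParams()]
#' @export
setClass("NeuronParams",
  representation(
    vRest = "numeric", vTh = "numeric", vReset = "numeric",
    tauM = "numeric", cM = "numeric", tRef = "numeric"
  )
)

setValidity("NeuronParams", function(object) {
  msg <- character()
  for (s in c("vRest", "vTh", "vReset", "tauM", "cM", "tRef")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
  }
  if (!length(msg)) {
    if (object@vReset >= object@vTh) {
      msg <- c(msg, "vReset must be below vTh")
    }
    if (object@tauM <= 0) msg <- c(msg, "tauM must be positive")
    if (object@cM <= 0) msg <- c(msg, "cM must be positive")
    if (object@tRef < 0) msg <- c(msg, "tRef must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Network configuration
#'
#' Complete description of the decision network: population sizes, membrane
#' parameters per cell class, the four receptor ports (NOISE, AMPA, NMDA,
#' GABA) with their synaptic time constants and conduction delays, the
#' dimensionless projection weights, per-projection connection
#' probabilities, the stimulus and background-noise statistics, and the
#' simulation step.
#'
#' All synaptic weights are expressed as dimensionless multipliers of the
#' common unitary PSP amplitude `J` (mV): the actual current amplitude of a
#' synapse is `pscAmplitude(target class, port tau) * J * w`.
#'
#' @slot sizes named integer vector `c(A=, B=, I=)` of population sizes.
#' @slot excParams,inhParams [NeuronParams-class] of the two cell classes.
#' @slot ports data.frame with columns `label`, `tauSyn` (ms), `delay` (ms),
#'   `sign` (+1/-1) for the NOISE, AMPA, NMDA and GABA channels.
#' @slot J unitary PSP amplitude (mV) targeted by the weight normalization.
#' @slot wPlus potentiated weight of within-population recurrent AMPA and of
#'   the excitatory-inhibitory projections.
#' @slot wMinus depressed weight of the cross-population excitatory
#'   projections (both receptor components).
#' @slot wNMDA weight of the within-population recurrent NMDA component.
#' @slot wWithinAMPA explicit weight of the within-population recurrent
#'   AMPA component; `NA` (the default) means "follow `wPlus`". Used by the
#'   reduced-potentiation ablation to scale the within-population recurrence
#'   without altering the excitatory-inhibitory pathway.
#' @slot wIE,wII weights of the GABA projections onto excitatory and
#'   inhibitory targets.
#' @slot wNoiseExc,wNoiseInh,wStim weights of the background-noise generators
#'   (per target class) and of the stimulus generators.
#' @slot epsEE,epsEI,epsIE,epsII pairwise-Bernoulli connection probabilities
#'   of the recurrent projection groups (E to E, E to I, I to E, I to I).
#' @slot potentiateWithinAMPA logical; if `TRUE` (default) the AMPA component
#'   of within-population recurrence carries `wPlus`, otherwise weight 1.
#' @slot mu0 total stimulus rate (Hz) split between the two generators.
#' @slot sigma0 SD (Hz) of the per-block Gaussian stimulus fluctuations.
#' @slot updateInterval stimulus resampling interval (ms).
#' @slot noiseExc,noiseInh `c(mean, sd)` (Hz) of the per-neuron Gaussian
#'   draw of background Poisson rates for each target class.
#' @slot dt simulation step (ms).
#'
#' @seealso [networkConfig()], [defaultConfig()], [projectionTable()]
#' @export
setClass("NetworkConfig",
  representation(
    sizes = "integer",
    excParams = "NeuronParams", inhParams = "NeuronParams",
    ports = "data.frame",
    J = "numeric",
    wPlus = "numeric", wMinus = "numeric", wNMDA = "numeric",
    wWithinAMPA = "numeric",
    wIE = "numeric", wII = "numeric",
    wNoiseExc = "numeric", wNoiseInh = "numeric", wStim = "numeric",
    epsEE = "numeric", epsEI = "numeric", epsIE = "numeric",
    epsII = "numeric",
    potentiateWithinAMPA = "logical",
    mu0 = "numeric", sigma0 = "numeric", updateInterval = "numeric",
    noiseExc = "numeric", noiseInh = "numeric",
    dt = "numeric"
  )
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (!identical(names(object@sizes), c("A", "B", "I"))) {
    msg <- c(msg, "sizes must be a named integer vector c(A=, B=, I=)")
  } else if (any(object@sizes < 1L)) {
    msg <- c(msg, "all population sizes must be at least 1")
  }
  p <- object@ports
  if (!identical(p$label, c("NOISE", "AMPA", "NMDA", "GABA"))) {
    msg <- c(msg, "ports must be NOISE, AMPA, NMDA, GABA in this order")
  } else {
    if (any(p$tauSyn <= 0)) msg <- c(msg, "every tauSyn must be positive")
    if (any(p$delay <= 0)) msg <- c(msg, "every delay must be positive")
    if (!all(p$sign == ifelse(p$label == "GABA", -1, 1))) {
      msg <- c(msg, "sign must be -1 exactly for the GABA port")
    }
    if (any(p$delay < object@dt)) {
      msg <- c(msg, "every delay must be at least one simulation step")
    }
  }
  for (s in c("epsEE", "epsEI", "epsIE", "epsII")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", s))
    }
  }
  if (object@J <= 0) msg <- c(msg, "J must be positive")
  if (length(object@wWithinAMPA) != 1L ||
    (!is.na(object@wWithinAMPA) && object@wWithinAMPA < 0)) {
    msg <- c(msg, "wWithinAMPA must be NA or a non-negative weight")
  }
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@mu0 < 0) msg <- c(msg, "mu0 must be non-negative")
  if (object@sigma0 < 0) msg <- c(msg, "sigma0 must be non-negative")
  if (object@updateInterval <= 0) {
    msg <- c(msg, "updateInterval must be positive")
  }
  for (s in c("noiseExc", "noiseInh")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] <= 0 || v[2] < 0) {
      msg <- c(msg, sprintf("'%s' must be c(mean > 0, sd >= 0)", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Trial protocol: timing and coherence schedule
#'
#' One trial consists of a pre-stimulus baseline (`tPre`), a stimulus epoch
#' (`tStim`) during which the two Poisson generators emit at
#' coherence-dependent rates, and a post-stimulus delay (`tPost`) during
#' which only the background noise remains. An optional reversal switches
#' the coherence from `coherence` to `coherenceAfter` at `reversalTime`
#' (measured from stimulus onset).
#'
#' @slot tPre,tStim,tPost epoch durations (ms), non-negative.
#' @slot coherence signed motion coherence in `[-1, 1]`; positive values
#'   favor population B, negative favor population A.
#' @slot reversalTime time of the coherence switch (ms after stimulus
#'   onset), or `numeric(0)` for no reversal; must lie in `[0, tStim]`.
#' @slot coherenceAfter coherence after the switch, `numeric(0)` if none.
#'
#' @seealso [trialProtocol()], [stimulusBlockCoherence()]
#' @export
setClass("TrialProtocol",
  representation(
    tPre = "numeric", tStim = "numeric", tPost = "numeric",
    coherence = "numeric",
    reversalTime = "numeric", coherenceAfter = "numeric"
  )
)

setValidity("TrialProtocol", function(object) {
  msg <- character()
  if (object@tPre < 0 || object@tStim < 0 || object@tPost < 0) {
    msg <- c(msg, "all epoch durations must be non-negative")
  }
  if (length(object@coherence) != 1L || abs(object@coherence) > 1) {
    msg <- c(msg, "coherence must be a single value in [-1, 1]")
  }
  if (length(object@reversalTime)) {
    if (object@reversalTime < 0 || object@reversalTime > object@tStim) {
      msg <- c(msg, "reversalTime must lie within [0, tStim]")
    }
    if (!length(object@coherenceAfter)) {
      msg <- c(msg, "a reversal needs 'coherenceAfter'")
    } else if (abs(object@coherenceAfter) > 1) {
      msg <- c(msg, "coherenceAfter must lie in [-1, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A built, ready-to-run network
#'
#' Concrete realization of a [NetworkConfig-class]: neurons laid out as
#' A, then B, then I, plus the realized pairwise-Bernoulli connectivity with
#' per-connection normalized current amplitudes, and an audit table of the
#' realized projection groups.
#'
#' @slot config the generating [NetworkConfig-class].
#' @slot pop 0-based population index per neuron (0 = A, 1 = B, 2 = I).
#' @slot connSrc,connTgt 0-based source / target neuron per connection.
#' @slot connPort 0-based receptor port per connection.
#' @slot connAmp signed PSC amplitude (pA) per connection.
#' @slot audit data.frame with one row per projection group: source, target,
#'   port, weight, connection probability, realized connection count and
#'   amplitude.
#' @slot buildSeed seed used for the connectivity draw (NA if built inside
#'   an externally seeded stream).
#'
#' @seealso [buildNetwork()], [runTrial()], [networkAudit()]
#' @export
setClass("DecisionNetwork",
  representation(
    config = "NetworkConfig",
    pop = "integer",
    connSrc = "integer", connTgt = "integer",
    connPort = "integer", connAmp = "numeric",
    audit = "data.frame",
    buildSeed = "numeric"
  )
)

#' Spike record of one simulated trial
#'
#' All spikes of one trial, together with the population layout and the
#' protocol context needed to analyze them. Times are in ms from trial
#' start; neuron ids are 1-based over the concatenated A, B, I layout.
#'
#' @slot time spike times (ms), non-decreasing.
#' @slot id 1-based neuron id per spike.
#' @slot population factor (levels A, B, I) per spike.
#' @slot sizes named integer vector of population sizes.
#' @slot duration trial duration (ms).
#' @slot stimOnset,stimEnd stimulus epoch (ms), NA if none.
#' @slot coherence signed coherence of the trial, NA if unknown.
#'
#' @seealso [runTrial()], [populationRate()], [writeSpikes()]
#' @export
setClass("SpikeTrains",
  representation(
    time = "numeric", id = "integer", population = "factor",
    sizes = "integer", duration = "numeric",
    stimOnset = "numeric", stimEnd = "numeric", coherence = "numeric"
  )
)

setValidity("SpikeTrains", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@id) != n || length(object@population) != n) {
    msg <- c(msg, "time, id and population must have equal length")
  }
  if (n && is.unsorted(object@time)) {
    msg <- c(msg, "spike times must be non-decreasing")
  }
  if (n && (min(object@time) < 0 || max(object@time) > object@duration)) {
    msg <- c(msg, "spike times must lie within [0, duration]")
  }
  if (!identical(names(object@sizes), c("A", "B", "I"))) {
    msg <- c(msg, "sizes must be named c(A=, B=, I=)")
  } else if (n && (min(object@id) < 1L || max(object@id) > sum(object@sizes))) {
    msg <- c(msg, "neuron ids must lie within the declared populations")
  }
  if (length(msg)) msg else TRUE
})

#' Population firing-rate trace
#'
#' Sliding-window estimate of a population's instantaneous firing rate in
#' spikes per neuron per second (Hz). The window is causal: the value at
#' time `t` counts spikes in `(t - window, t]`.
#'
#' @slot times right edges of the sliding windows (ms).
#' @slot rate rate estimate (Hz) per grid point.
#' @slot population population label.
#' @slot nNeurons number of neurons the count was normalized by.
#' @slot window,step window length and grid step (ms).
#'
#' @seealso [populationRate()], [classifyDecision()], [decisionSpace()]
#' @export
setClass("RateTrace",
  representation(
    times = "numeric", rate = "numeric", population = "character",
    nNeurons = "integer", window = "numeric", step = "numeric"
  )
)

setValidity("RateTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@rate)) {
    msg <- c(msg, "times and rate must have equal length")
  }
  if (any(object@rate < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Classified outcome of one trial
#'
#' Decision readout of one trial under the threshold rule: the winner is the
#' first population whose smoothed rate sustains the decision threshold
#' after stimulus onset; the decision time is measured from stimulus onset.
#'
#' @slot winner `"A"`, `"B"` or `"none"`.
#' @slot decisionTime ms from stimulus onset to the threshold crossing
#'   (NA when undecided).
#' @slot coherence the trial's signed coherence.
#' @slot correct `TRUE` when the winner matches the stimulated direction;
#'   NA when undecided or when coherence is 0 (no correct answer exists).
#' @slot persisted `TRUE` when the winner's rate stays above the loser's
#'   throughout the post-stimulus delay; NA when undecided or no delay.
#' @slot delayRatio winner's mean rate over the last 500 ms of the delay
#'   divided by its peak stimulus-epoch rate (persistence strength; NA when
#'   undecided).
#' @slot tie `TRUE` when both populations crossed in the same window (the
#'   tie was broken by rate, then by label).
#' @slot threshold decision threshold used (Hz).
#'
#' @seealso [classifyDecision()], [classifyTrial()]
#' @export
setClass("TrialOutcome",
  representation(
    winner = "character", decisionTime = "numeric", coherence = "numeric",
    correct = "logical", persisted = "logical", delayRatio = "numeric",
    tie = "logical", threshold = "numeric"
  )
)

#' Weibull fit of a neurometric function
#'
#' Least-squares fit of `pct = 1 - 0.5 * exp(-(c / alpha) ^ beta)` to
#' percent-correct versus coherence (in percent units).
#'
#' @slot alpha,beta fitted scale (percent coherence) and shape.
#' @slot coherences,pctCorrect the fitted data.
#' @slot residuals fit residuals.
#' @slot converged `FALSE` when the data were degenerate (all at chance or
#'   all saturated) or the optimizer failed; `alpha`/`beta` are NA then.
#'
#' @seealso [fitWeibull()], [weibullPercentCorrect()]
#' @export
setClass("NeurometricFit",
  representation(
    alpha = "numeric", beta = "numeric",
    coherences = "numeric", pctCorrect = "numeric",
    residuals = "numeric", converged = "logical"
  )
)
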