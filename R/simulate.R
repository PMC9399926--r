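#' @include AllClasses.R AllGenerics.R network.R stimulus.R
NULL

# marshal a built network + protocol into the C++ kernel; assumes the four
# RNG substreams are applied by the caller in the documented order
.runBuilt <- function(network, protocol, seeds) {
  config <- network@config
  validObject(protocol)
  sizes <- config@sizes
  n <- sum(sizes)
  isE <- network@pop < 2L
  exc <- config@excParams
  inh <- config@inhParams
  perNeuron <- function(slotName) {
    ifelse(isE, slot(exc, slotName), slot(inh, slotName))
  }
  dt <- config@dt
  nSteps <- as.integer(round(duration(protocol) / dt))
  ports <- config@ports
  delaySteps <- as.integer(round(ports$delay / dt))
  if (any(delaySteps < 1L)) {
    stop("every port delay must be at least one simulation step")
  }

  # background rates: one Gaussian draw per neuron, A, B then I
  set.seed(seeds[["background"]])
  noiseRate <- numeric(n)
  noiseRate[isE] <- sampleBackgroundRates(
    sum(isE), config@noiseExc[1], config@noiseExc[2]
  )
  noiseRate[!isE] <- sampleBackgroundRates(
    sum(!isE), config@noiseInh[1], config@noiseInh[2]
  )
  noisePort <- .portIndex(ports, "NOISE")
  noiseAmp <- ifelse(
    isE,
    pscAmplitude(exc, ports$tauSyn[noisePort]) * config@J * config@wNoiseExc,
    pscAmplitude(inh, ports$tauSyn[noisePort]) * config@J * config@wNoiseInh
  )

  # stimulus traces: per-block Gaussian draws expanded to per-step rates
  set.seed(seeds[["stimulus"]])
  stim <- sampleStimulusPair(
    protocol, config@mu0, config@sigma0, config@updateInterval
  )
  rateA <- rateB <- numeric(nSteps)
  if (nrow(stim) && protocol@tStim > 0) {
    blockSteps <- as.integer(round(config@updateInterval / dt))
    stimSteps <- as.integer(round(protocol@tStim / dt))
    i0 <- as.integer(round(protocol@tPre / dt))
    idx <- seq_len(stimSteps)
    block <- pmin((idx - 1L) %/% blockSteps + 1L, nrow(stim))
    rateA[i0 + idx] <- stim$rateA[block]
    rateB[i0 + idx] <- stim$rateB[block]
  }
  stimPort <- .portIndex(ports, "AMPA")
  stimAmp <- ifelse(
    isE, pscAmplitude(exc, ports$tauSyn[stimPort]) * config@J * config@wStim,
    0
  )

  set.seed(seeds[["simulation"]])
  res <- .simulate_trial_cpp(
    network@pop,
    perNeuron("vRest"), perNeuron("tauM"), perNeuron("cM"),
    perNeuron("vTh"), perNeuron("vReset"), perNeuron("tRef"),
    ports$tauSyn, delaySteps,
    network@connSrc, network@connTgt, network@connPort, network@connAmp,
    noiseRate, noiseAmp, noisePort - 1L,
    rateA, rateB, stimAmp, stimPort - 1L,
    matrix(0, 0, 4), dt, nSteps, integer(0), numeric(0)
  )
  popLabels <- factor(
    c("A", "B", "I")[network@pop[res$neuron_id] + 1L],
    levels = c("A", "B", "I")
  )
  ord <- order(res$time_ms, res$neuron_id)
  new("SpikeTrains",
    time = res$time_ms[ord], id = res$neuron_id[ord],
    population = popLabels[ord],
    sizes = sizes, duration = nSteps * dt,
    stimOnset = if (protocol@tStim > 0) protocol@tPre else NA_real_,
    stimEnd = if (protocol@tStim > 0) protocol@tPre + protocol@tStim else NA_real_,
    coherence = protocol@coherence
  )
}

#' @describeIn runTrial rebuild the connectivity from the seed's
#'   connectivity substream, then simulate. Every trial therefore carries an
#'   independent wiring realization, as in the batch experiments.
#' @export
setMethod("runTrial", "NetworkConfig", function(x, protocol, seed, ...) {
  seeds <- deriveSeeds(seed)
  set.seed(seeds[["connectivity"]])
  network <- buildNetwork(x)
  .runBuilt(network, protocol, seeds)
})

#' @describeIn runTrial reuse an already-built network (the connectivity
#'   substream is derived but left unused).
#' @export
setMethod("runTrial", "DecisionNetwork", function(x, protocol, seed, ...) {
  seeds <- deriveSeeds(seed)
  .runBuilt(x, protocol, seeds)
})

#' @describeIn runTrial number of spikes in the record
#' @param x a `SpikeTrains`.
#' @export
setMethod("nNeurons", "SpikeTrains", function(x) sum(x@sizes))

#' @describeIn runTrial named population sizes
#' @export
setMethod("populations", "SpikeTrains", function(x) x@sizes)

#' @describeIn runTrial trial duration (ms)
#' @export
setMethod("duration", "SpikeTrains", function(x) x@duration)

#' @describeIn runTrial display method
#' @param object a `SpikeTrains`.
#' @export
setMethod("show", "SpikeTrains", function(object) {
  cat(sprintf(
    "SpikeTrains: %d spikes from %d neurons over %g ms",
    length(object@time), sum(object@sizes), object@duration
  ))
  if (!is.na(object@coherence)) {
    cat(sprintf(
      "; stimulus %+.1f%% in [%g, %g] ms", 100 * object@coherence,
      object@stimOnset, object@stimEnd
    ))
  }
  cat("\n")
  if (length(object@time)) {
    counts <- table(object@population)
    rates <- counts / object@sizes[names(counts)] / object@duration * 1000
    cat(sprintf(
      "  mean rates: A %.2f Hz, B %.2f Hz, I %.2f Hz\n",
      rates["A"], rates["B"], rates["I"]
    ))
  }
})

#' @describeIn runTrial spike record as a data.frame with columns
#'   `time_ms`, `neuron_id`, `population`
#' @param row.names,optional ignored (S3 compatibility).
#' @export
as.data.frame.SpikeTrains <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(
    time_ms = x@time, neuron_id = x@id, population = x@population
  )
}
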