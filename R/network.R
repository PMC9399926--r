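#' Construct membrane parameters
#'
#' @param vRest,vTh,vReset potentials (mV).
#' @param tauM membrane time constant (ms).
#' @param cM capacitance (pF).
#' @param tRef refractory period (ms).
#' @return a [NeuronParams-class].
#' @examples
#' neuronParams(-70, -50, -55, 20, 500, 2) # excitatory cell class
#' @export
neuronParams <- function(vRest, vTh, vReset, tauM, cM, tRef) {
  new("NeuronParams",
    vRest = as.numeric(vRest), vTh = as.numeric(vTh),
    vReset = as.numeric(vReset), tauM = as.numeric(tauM),
    cM = as.numeric(cM), tRef = as.numeric(tRef)
  )
}

#' @describeIn neuronParams display method
#' @param object a `NeuronParams`.
#' @export
setMethod("show", "NeuronParams", function(object) {
  cat(sprintf(
    "NeuronParams: vRest %g mV, vTh %g mV, vReset %g mV, tauM %g ms, cM %g pF, tRef %g ms\n",
    object@vRest, object@vTh, object@vReset, object@tauM, object@cM,
    object@tRef
  ))
})

.defaultPorts <- function() {
  data.frame(
    label = c("NOISE", "AMPA", "NMDA", "GABA"),
    tauSyn = c(5, 2, 100, 5),
    delay = c(0.5, 0.5, 2.5, 0.5),
    sign = c(1, 1, 1, -1),
    stringsAsFactors = FALSE
  )
}

# Reference connection probabilities, calibrated once for the 1,000-neuron
# network (A = B = 400, I = 200) and rescaled inversely with population size
# so that expected in-degrees -- and therefore the mean synaptic drive per
# neuron -- are preserved when the network is scaled up or down.
.epsRef <- c(EE = 0.03, EI = 0.025, IE = 0.1, II = 0.1)
.refSizes <- c(A = 400L, B = 400L, I = 200L)

#' Network configuration with the standard parameterization
#'
#' `defaultConfig()` (alias `networkConfig()`) returns the standard
#' parameter set of the decision network: populations A = B = 800, I = 400
#' (scaled by `scale` while preserving the 2:2:1 ratio); membrane constants
#' per cell class (excitatory: -70/-50/-55 mV, 20 ms, 500 pF, 2 ms;
#' inhibitory: -70/-50/-55 mV, 10 ms, 200 pF, 1 ms); unitary PSP amplitude
#' J = 0.04 mV; projection weights w+ = 1.7, w- = 0.8, wNMDA = 4.25;
#' receptor channels NOISE/AMPA/NMDA/GABA with synaptic time constants
#' 5/2/100/5 ms and delays 0.5/0.5/2.5/0.5 ms; stimulus mu0 = 772 Hz with
#' sigma0 = 48 Hz resampled every 25 ms; background noise 7719 +- 38 Hz to
#' excitatory and 5789 +- 28 Hz to inhibitory neurons; dt = 0.1 ms.
#'
#' The connection probabilities and the weights of the inhibitory and
#' generator projections are not pinned down by the standard parameterization;
#' their defaults were calibrated once so that the network operates in the
#' regime the model describes (sparse spontaneous activity, interneurons at
#' a few Hz, stimulus-driven winner-take-all reaching a 25-35 Hz attractor
#' with post-stimulus persistence and no saturation). Connection
#' probabilities are expressed at the 1,000-neuron reference scale and
#' scaled inversely with population size so in-degrees are preserved.
#'
#' @param scale size multiplier applied to the 800/800/400 layout
#'   (e.g. `scale = 0.5` gives the 1,000-neuron network).
#' @param ... named overrides of any [NetworkConfig-class] slot, e.g.
#'   `wPlus = 1.4`, `sigma0 = 0`, `epsEE = 0.05`.
#' @return a validated [NetworkConfig-class].
#' @examples
#' cfg <- defaultConfig(scale = 0.5)
#' sum(populations(cfg)) # 1000 neurons
#' @export
defaultConfig <- function(scale = 1, ...) {
  sizes <- as.integer(round(c(A = 800, B = 800, I = 400) * scale))
  names(sizes) <- c("A", "B", "I")
  eps <- c(
    EE = unname(.epsRef["EE"] * .refSizes["A"] / sizes["A"]),
    EI = unname(.epsRef["EI"] * .refSizes["A"] / sizes["A"]),
    IE = unname(.epsRef["IE"] * .refSizes["I"] / sizes["I"]),
    II = unname(.epsRef["II"] * .refSizes["I"] / sizes["I"])
  )
  cfg <- new("NetworkConfig",
    sizes = sizes,
    excParams = neuronParams(-70, -50, -55, 20, 500, 2),
    inhParams = neuronParams(-70, -50, -55, 10, 200, 1),
    ports = .defaultPorts(),
    J = 0.04,
    wPlus = 1.7, wMinus = 0.8, wNMDA = 4.25,
    wWithinAMPA = NA_real_,
    wIE = 8, wII = 1,
    wNoiseExc = 1.9, wNoiseInh = 3.85, wStim = 1,
    epsEE = min(1, eps[["EE"]]), epsEI = min(1, eps[["EI"]]),
    epsIE = min(1, eps[["IE"]]), epsII = min(1, eps[["II"]]),
    potentiateWithinAMPA = TRUE,
    mu0 = 772, sigma0 = 48, updateInterval = 25,
    noiseExc = c(7719, 38), noiseInh = c(5789, 28),
    dt = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), slotNames("NetworkConfig"))
    if (length(bad)) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    for (nm in names(dots)) {
      value <- dots[[nm]]
      if (nm == "sizes") value <- structure(as.integer(value), names = c("A", "B", "I"))
      slot(cfg, nm) <- value
    }
    validObject(cfg)
  }
  cfg
}

#' @rdname defaultConfig
#' @export
networkConfig <- defaultConfig

#' @describeIn defaultConfig total neuron count of a configuration
#' @param x a `NetworkConfig`.
#' @export
setMethod("nNeurons", "NetworkConfig", function(x) sum(x@sizes))

#' @describeIn defaultConfig named population sizes
#' @export
setMethod("populations", "NetworkConfig", function(x) x@sizes)

#' @describeIn defaultConfig display method
#' @param object a `NetworkConfig`.
#' @export
setMethod("show", "NetworkConfig", function(object) {
  s <- object@sizes
  cat(sprintf(
    "NetworkConfig: %d neurons (A=%d, B=%d, I=%d)\n", sum(s), s["A"],
    s["B"], s["I"]
  ))
  cat(sprintf(
    "  weights: J=%g mV, w+=%g, w-=%g, wNMDA=%g, wIE=%g, wII=%g\n",
    object@J, object@wPlus, object@wMinus, object@wNMDA, object@wIE,
    object@wII
  ))
  cat(sprintf(
    "  epsilon: EE=%.4g, EI=%.4g, IE=%.4g, II=%.4g\n",
    object@epsEE, object@epsEI, object@epsIE, object@epsII
  ))
  cat(sprintf(
    "  stimulus: mu0=%g Hz, sigma0=%g Hz every %g ms; noise %g+-%g / %g+-%g Hz\n",
    object@mu0, object@sigma0, object@updateInterval, object@noiseExc[1],
    object@noiseExc[2], object@noiseInh[1], object@noiseInh[2]
  ))
  cat(sprintf("  dt=%g ms\n", object@dt))
})

#' Projection table of the decision network
#'
#' Expands a configuration into the full list of projection groups wired by
#' [buildNetwork()]. Every excitatory projection carries both an AMPA and an
#' NMDA component: within-population recurrence at `wPlus` (AMPA; weight 1
#' if `potentiateWithinAMPA` is off) and `wNMDA` (NMDA); cross-population
#' excitation depressed by `wMinus` on both components; projections onto the
#' interneurons potentiated by `wPlus` on both components. Inhibition is
#' GABA-mediated at `wIE` (onto excitatory cells) and `wII` (recurrent).
#' The generator rows describe the per-neuron background-noise wiring
#' (NOISE port, all populations) and the stimulus wiring (AMPA port, one
#' generator per excitatory population); generators attach per target
#' neuron, not through the Bernoulli rule, so their `epsilon` is NA.
#'
#' @param config a [NetworkConfig-class].
#' @return data.frame with columns `source`, `target`, `port`, `epsilon`,
#'   `w` and `generator`.
#' @examples
#' tab <- projectionTable(defaultConfig())
#' subset(tab, source == "A" & target == "A" & port == "NMDA")$w # 4.25
#' @export
projectionTable <- function(config) {
  stopifnot(is(config, "NetworkConfig"))
  wWithinAMPA <- if (!is.na(config@wWithinAMPA)) {
    config@wWithinAMPA
  } else if (config@potentiateWithinAMPA) {
    config@wPlus
  } else {
    1
  }
  rec <- rbind(
    data.frame(source = "A", target = "A", port = "AMPA", epsilon = config@epsEE, w = wWithinAMPA),
    data.frame(source = "A", target = "A", port = "NMDA", epsilon = config@epsEE, w = config@wNMDA),
    data.frame(source = "B", target = "B", port = "AMPA", epsilon = config@epsEE, w = wWithinAMPA),
    data.frame(source = "B", target = "B", port = "NMDA", epsilon = config@epsEE, w = config@wNMDA),
    data.frame(source = "A", target = "B", port = "AMPA", epsilon = config@epsEE, w = config@wMinus),
    data.frame(source = "A", target = "B", port = "NMDA", epsilon = config@epsEE, w = config@wMinus),
    data.frame(source = "B", target = "A", port = "AMPA", epsilon = config@epsEE, w = config@wMinus),
    data.frame(source = "B", target = "A", port = "NMDA", epsilon = config@epsEE, w = config@wMinus),
    data.frame(source = "A", target = "I", port = "AMPA", epsilon = config@epsEI, w = config@wPlus),
    data.frame(source = "A", target = "I", port = "NMDA", epsilon = config@epsEI, w = config@wPlus),
    data.frame(source = "B", target = "I", port = "AMPA", epsilon = config@epsEI, w = config@wPlus),
    data.frame(source = "B", target = "I", port = "NMDA", epsilon = config@epsEI, w = config@wPlus),
    data.frame(source = "I", target = "A", port = "GABA", epsilon = config@epsIE, w = config@wIE),
    data.frame(source = "I", target = "B", port = "GABA", epsilon = config@epsIE, w = config@wIE),
    data.frame(source = "I", target = "I", port = "GABA", epsilon = config@epsII, w = config@wII)
  )
  rec$generator <- FALSE
  gen <- rbind(
    data.frame(source = "noise", target = "A", port = "NOISE", epsilon = NA_real_, w = config@wNoiseExc),
    data.frame(source = "noise", target = "B", port = "NOISE", epsilon = NA_real_, w = config@wNoiseExc),
    data.frame(source = "noise", target = "I", port = "NOISE", epsilon = NA_real_, w = config@wNoiseInh),
    data.frame(source = "stimA", target = "A", port = "AMPA", epsilon = NA_real_, w = config@wStim),
    data.frame(source = "stimB", target = "B", port = "AMPA", epsilon = NA_real_, w = config@wStim)
  )
  gen$generator <- TRUE
  rbind(rec, gen)
}

.popRanges <- function(sizes) {
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  list(
    A = starts[1]:ends[1],
    B = starts[2]:ends[2],
    I = starts[3]:ends[3]
  )
}

.portIndex <- function(ports, label) match(label, ports$label)

.classParams <- function(config, popLabel) {
  if (popLabel == "I") config@inhParams else config@excParams
}

#' @describeIn buildNetwork realize the connectivity of a configuration.
#'   Connectivity is drawn from the current RNG stream; pass `seed` to make
#'   the draw self-contained.
#' @param seed optional integer seed for the connectivity draw.
#' @export
setMethod("buildNetwork", "NetworkConfig", function(config, seed = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sizes <- config@sizes
  ranges <- .popRanges(sizes)
  tab <- projectionTable(config)
  rec <- tab[!tab$generator, ]
  src <- tgt <- port <- integer(0)
  amp <- numeric(0)
  counts <- integer(nrow(rec))
  amps <- numeric(nrow(rec))
  for (k in seq_len(nrow(rec))) {
    g <- rec[k, ]
    sIds <- ranges[[g$source]]
    tIds <- ranges[[g$target]]
    pairs <- connectPairwiseBernoulli(
      length(sIds), length(tIds), g$epsilon,
      sameOrigin = identical(g$source, g$target)
    )
    pIdx <- .portIndex(config@ports, g$port)
    a <- pscAmplitude(
      .classParams(config, g$target),
      config@ports$tauSyn[pIdx]
    ) * config@J * g$w * config@ports$sign[pIdx]
    src <- c(src, sIds[pairs$source])
    tgt <- c(tgt, tIds[pairs$target])
    port <- c(port, rep(pIdx, nrow(pairs)))
    amp <- c(amp, rep(a, nrow(pairs)))
    counts[k] <- nrow(pairs)
    amps[k] <- a
  }
  audit <- rec
  audit$nConnections <- counts
  audit$amplitude_pA <- amps
  new("DecisionNetwork",
    config = config,
    pop = rep(0:2, times = sizes),
    connSrc = as.integer(src - 1L), connTgt = as.integer(tgt - 1L),
    connPort = as.integer(port - 1L), connAmp = amp,
    audit = audit,
    buildSeed = if (is.null(seed)) NA_real_ else as.numeric(seed)
  )
})

#' @describeIn buildNetwork total neuron count
#' @param x a `DecisionNetwork`.
#' @export
setMethod("nNeurons", "DecisionNetwork", function(x) sum(x@config@sizes))

#' @describeIn buildNetwork named population sizes
#' @export
setMethod("populations", "DecisionNetwork", function(x) x@config@sizes)

#' @describeIn buildNetwork display method
#' @param object a `DecisionNetwork`.
#' @export
setMethod("show", "DecisionNetwork", function(object) {
  s <- object@config@sizes
  cat(sprintf(
    "DecisionNetwork: %d neurons (A=%d, B=%d, I=%d), %d connections in %d groups\n",
    sum(s), s["A"], s["B"], s["I"], length(object@connSrc),
    nrow(object@audit)
  ))
})

#' Audit summary of a built network
#'
#' @param network a [DecisionNetwork-class].
#' @return list with the population sizes, the port table and the realized
#'   projection groups (weight, probability, connection count, normalized
#'   amplitude), suitable for JSON export via [writeNetworkAudit()].
#' @export
networkAudit <- function(network) {
  stopifnot(is(network, "DecisionNetwork"))
  list(
    sizes = as.list(network@config@sizes),
    ports = network@config@ports,
    groups = network@audit,
    nConnections = length(network@connSrc)
  )
}
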