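#' Mean stimulus rates for a coherence level
#'
#' The two motion-direction generators share the total rate `mu0` through
#' the symmetric linear model `muA = mu0 * (0.5 - 0.5 c)` and
#' `muB = mu0 * (0.5 + 0.5 c)`, so that `muA + muB = mu0` for every
#' coherence. Positive coherence favors population B.
#'
#' @param mu0 total stimulus rate (Hz).
#' @param coherence signed coherence in `[-1, 1]` (fraction, not percent).
#' @return named numeric vector `c(A=, B=)` of mean rates (Hz).
#' @examples
#' coherenceToMeans(771, 0.032) # c(A = 373.164, B = 397.836)
#' @export
coherenceToMeans <- function(mu0, coherence) {
  if (!is.numeric(coherence) || length(coherence) != 1L ||
    is.na(coherence) || abs(coherence) > 1) {
    stop("'coherence' must be a single value in [-1, 1]")
  }
  if (!is.numeric(mu0) || length(mu0) != 1L || mu0 < 0) {
    stop("'mu0' must be a single non-negative rate (Hz)")
  }
  c(A = mu0 * (0.5 - 0.5 * coherence), B = mu0 * (0.5 + 0.5 * coherence))
}

#' Piecewise-constant stimulus rate trace
#'
#' One Gaussian draw `N(mean, sigma0^2)` per update block, clipped at zero.
#' With `sigma0 = 0` the trace is deterministic and equal to `mean` -- the
#' mode used to remove stimulus fluctuations in the coin-toss experiment.
#'
#' @param mean block mean (Hz), non-negative.
#' @param sigma0 block SD (Hz), non-negative.
#' @param tStim stimulus duration (ms).
#' @param updateInterval block length (ms), default 25.
#' @return numeric vector of `ceiling(tStim / updateInterval)` block rates.
#' @export
sampleStimulusTrace <- function(mean, sigma0, tStim, updateInterval = 25) {
  stopifnot(mean >= 0, sigma0 >= 0, tStim >= 0, updateInterval > 0)
  nBlocks <- ceiling(tStim / updateInterval)
  if (nBlocks == 0) return(numeric(0))
  if (sigma0 == 0) return(rep(mean, nBlocks))
  pmax(rnorm(nBlocks, mean, sigma0), 0)
}

#' Per-neuron background-noise rates
#'
#' Each neuron's background Poisson rate is one Gaussian draw
#' `N(mu, sigma^2)`, clipped at zero, held fixed for the whole trial.
#'
#' @param nNeurons number of draws.
#' @param mu mean rate (Hz), positive.
#' @param sigma SD (Hz), non-negative.
#' @return numeric vector of per-neuron rates (Hz).
#' @export
sampleBackgroundRates <- function(nNeurons, mu, sigma) {
  stopifnot(nNeurons >= 0, mu > 0, sigma >= 0)
  if (nNeurons == 0) return(numeric(0))
  if (sigma == 0) return(rep(mu, nNeurons))
  pmax(rnorm(nNeurons, mu, sigma), 0)
}

#' Construct a trial protocol
#'
#' @param coherence signed coherence in `[-1, 1]`; positive favors B.
#' @param tPre,tStim,tPost epoch durations (ms); the defaults give the
#'   standard 3 s trial (500 ms baseline, 1 s stimulus, 1.5 s delay).
#' @param reversalTime optional coherence-switch time (ms from stimulus
#'   onset), within `[0, tStim]`.
#' @param coherenceAfter coherence after the switch.
#' @return a validated [TrialProtocol-class].
#' @examples
#' trialProtocol(-0.064, reversalTime = 700, coherenceAfter = 0.064)
#' @export
trialProtocol <- function(coherence = 0, tPre = 500, tStim = 1000,
                          tPost = 1500, reversalTime = NULL,
                          coherenceAfter = NULL) {
  new("TrialProtocol",
    tPre = as.numeric(tPre), tStim = as.numeric(tStim),
    tPost = as.numeric(tPost), coherence = as.numeric(coherence),
    reversalTime = if (is.null(reversalTime)) numeric(0) else as.numeric(reversalTime),
    coherenceAfter = if (is.null(coherenceAfter)) numeric(0) else as.numeric(coherenceAfter)
  )
}

#' @describeIn trialProtocol total trial duration (ms)
#' @param x a `TrialProtocol`.
#' @export
setMethod("duration", "TrialProtocol", function(x) x@tPre + x@tStim + x@tPost)

#' @describeIn trialProtocol display method
#' @param object a `TrialProtocol`.
#' @export
setMethod("show", "TrialProtocol", function(object) {
  cat(sprintf(
    "TrialProtocol: %g + %g + %g ms, coherence %+.1f%%",
    object@tPre, object@tStim, object@tPost, 100 * object@coherence
  ))
  if (length(object@reversalTime)) {
    cat(sprintf(
      ", reversed to %+.1f%% at %g ms", 100 * object@coherenceAfter,
      object@reversalTime
    ))
  }
  cat("\n")
})

#' Coherence in effect for each stimulus block
#'
#' Expands a protocol's coherence schedule into one value per update block:
#' blocks starting at or after `reversalTime` use `coherenceAfter`.
#'
#' @param protocol a [TrialProtocol-class].
#' @param updateInterval block length (ms).
#' @return numeric vector of per-block coherences (length
#'   `ceiling(tStim / updateInterval)`).
#' @export
stimulusBlockCoherence <- function(protocol, updateInterval = 25) {
  stopifnot(is(protocol, "TrialProtocol"))
  nBlocks <- ceiling(protocol@tStim / updateInterval)
  if (nBlocks == 0) return(numeric(0))
  blockStart <- (seq_len(nBlocks) - 1) * updateInterval
  cc <- rep(protocol@coherence, nBlocks)
  if (length(protocol@reversalTime)) {
    cc[blockStart >= protocol@reversalTime] <- protocol@coherenceAfter
  }
  cc
}

#' Sampled stimulus traces for one trial
#'
#' Draws the per-block rates of the two stimulus generators under a
#' protocol (one Gaussian draw per block per generator, A drawn first,
#' then B), honoring a mid-stimulus coherence reversal.
#'
#' @param protocol a [TrialProtocol-class].
#' @param mu0,sigma0 stimulus statistics (Hz).
#' @param updateInterval block length (ms).
#' @return data.frame with columns `blockStart` (ms from stimulus onset),
#'   `coherence`, `rateA`, `rateB`.
#' @export
sampleStimulusPair <- function(protocol, mu0, sigma0, updateInterval = 25) {
  cc <- stimulusBlockCoherence(protocol, updateInterval)
  nBlocks <- length(cc)
  means <- vapply(cc, function(ci) coherenceToMeans(mu0, ci), numeric(2))
  rateA <- if (sigma0 == 0) means[1, ] else pmax(rnorm(nBlocks, means[1, ], sigma0), 0)
  rateB <- if (sigma0 == 0) means[2, ] else pmax(rnorm(nBlocks, means[2, ], sigma0), 0)
  data.frame(
    blockStart = (seq_len(nBlocks) - 1) * updateInterval,
    coherence = cc,
    rateA = as.numeric(rateA), rateB = as.numeric(rateB)
  )
}
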