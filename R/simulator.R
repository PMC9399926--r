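#' Peak-normalized postsynaptic current amplitude
#'
#' Computes the amplitude (pA) of an exponential postsynaptic current such
#' that a single presynaptic spike deflects the target membrane by a peak of
#' exactly 1 mV. Callers scale the result by the unitary PSP amplitude `J`
#' (mV) and the dimensionless projection weight `w`.
#'
#' For a current `I(t) = A exp(-t/tau_s)` injected into a passive membrane
#' with time constant `tau_m` and capacitance `C_m`, the PSP is
#' `A * tau_m tau_s / (C_m (tau_m - tau_s)) * (exp(-t/tau_m) - exp(-t/tau_s))`,
#' peaking at `t* = tau_m tau_s / (tau_m - tau_s) * log(tau_m / tau_s)`.
#' The returned amplitude is the reciprocal of that peak. In the singular
#' limit `tau_s == tau_m == tau` the PSP is the alpha function
#' `A t exp(-t/tau) / C_m`, peaking at `t = tau`, and the amplitude is
#' `C_m e / tau`; the limit formula is used when the two constants are
#' within 1e-9 ms.
#'
#' @param params a [NeuronParams-class] describing the target membrane.
#' @param tauSyn synaptic decay time constant (ms), positive.
#' @return peak current amplitude (pA) for a 1 mV peak PSP.
#' @examples
#' exc <- neuronParams(-70, -50, -55, tauM = 20, cM = 500, tRef = 2)
#' pscAmplitude(exc, 2) * 0.04 # AMPA amplitude for a 0.04 mV PSP
#' @export
pscAmplitude <- function(params, tauSyn) {
  stopifnot(is(params, "NeuronParams"))
  if (!is.numeric(tauSyn) || length(tauSyn) != 1L || tauSyn <= 0) {
    stop("'tauSyn' must be a single positive time constant (ms)")
  }
  tm <- params@tauM
  cm <- params@cM
  if (abs(tm - tauSyn) < 1e-9) {
    return(cm * exp(1) / tauSyn)
  }
  tstar <- tm * tauSyn / (tm - tauSyn) * log(tm / tauSyn)
  peak <- tm * tauSyn / (cm * (tm - tauSyn)) *
    (exp(-tstar / tm) - exp(-tstar / tauSyn))
  1 / peak
}

#' Homogeneous Poisson spike times
#'
#' Draws one realization of a homogeneous Poisson process on
#' `[tStart, tStop)` by accumulating exponential inter-spike intervals from
#' the current RNG stream. Each target neuron of a Poisson generator
#' receives its own independent realization (shared identical trains would
#' synchronize the population artificially).
#'
#' @param rate rate (Hz), non-negative.
#' @param tStart,tStop interval bounds (ms), `tStop >= tStart`.
#' @return numeric vector of spike times (ms) in increasing order.
#' @export
generatePoissonSpikes <- function(rate, tStart = 0, tStop = 1000) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("'rate' must be a single non-negative number (Hz)")
  }
  if (tStop < tStart) stop("'tStop' must not precede 'tStart'")
  if (rate == 0 || tStop == tStart) return(numeric(0))
  span <- tStop - tStart
  # draw in chunks of mean + 6 sd until past tStop
  expected <- rate * span / 1000
  times <- numeric(0)
  last <- 0
  repeat {
    k <- max(16L, ceiling(expected - length(times) + 6 * sqrt(expected)))
    gaps <- rexp(k, rate / 1000)
    times <- c(times, last + cumsum(gaps))
    last <- times[length(times)]
    if (last >= span) break
  }
  tStart + times[times < span]
}

#' Pairwise-Bernoulli connectivity
#'
#' Connects each ordered (source, target) pair independently with
#' probability `p`. When source and target index the same population
#' (`sameOrigin = TRUE`), self-connections are excluded. At most one
#' connection is created per ordered pair.
#'
#' @param nSource,nTarget population sizes.
#' @param p connection probability in `[0, 1]`.
#' @param sameOrigin `TRUE` when the two populations are the same, so that
#'   autapses must be excluded.
#' @return data.frame with integer columns `source` and `target`
#'   (1-based within their populations).
#' @export
connectPairwiseBernoulli <- function(nSource, nTarget, p,
                                     sameOrigin = FALSE) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("'p' must be a single probability in [0, 1]")
  }
  stopifnot(nSource >= 0, nTarget >= 0)
  if (p == 0 || nSource == 0 || nTarget == 0) {
    return(data.frame(source = integer(0), target = integer(0)))
  }
  hit <- which(runif(nSource * nTarget) < p)
  src <- (hit - 1L) %% nSource + 1L
  tgt <- (hit - 1L) %/% nSource + 1L
  if (sameOrigin) {
    keep <- src != tgt
    src <- src[keep]
    tgt <- tgt[keep]
  }
  data.frame(source = src, target = tgt)
}

#' Expand a master seed into per-stream seeds
#'
#' A single master seed is expanded into four named substream seeds drawn
#' from a seeded stream, in this fixed order: `connectivity` (Bernoulli
#' wiring), `background` (per-neuron noise rates), `stimulus` (per-block
#' stimulus rates), `simulation` (per-step Poisson sampling inside the
#' kernel). The ordering is part of the reproducibility contract: any two
#' runs with the same master seed consume identical randomness in every
#' stage, independently of how the stages are interleaved by the caller.
#'
#' @param seed integer master seed.
#' @return named integer vector of four substream seeds.
#' @export
deriveSeeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("connectivity", "background", "stimulus", "simulation")
  s
}
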