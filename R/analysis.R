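#' @include AllClasses.R AllGenerics.R simulate.R
NULL

#' @describeIn populationRate sliding-window rate of one population.
#'
#' The estimate at grid time `t` is the spike count in the causal window
#' `(t - window, t]`, divided by `nNeurons * window` (always the full window
#' length, so the first `window` ms ramp up from zero). An optional 3-point
#' running-median filter removes single-window noise spikes.
#'
#' @param window window length (ms).
#' @param step grid step (ms).
#' @param medianFilter odd filter width in grid points (e.g. 3), or `NULL`
#'   for the raw trace.
#' @export
setMethod("populationRate", "SpikeTrains", function(x, population,
                                                    window = 50, step = 5,
                                                    medianFilter = NULL) {
  if (!population %in% c("A", "B", "I")) {
    stop("unknown population label: ", population)
  }
  stopifnot(window > 0, step > 0)
  ts <- sort(x@time[x@population == population])
  grid <- seq(step, x@duration, by = step)
  counts <- findInterval(grid, ts) - findInterval(grid - window, ts)
  rate <- counts / (x@sizes[[population]] * window) * 1000
  if (!is.null(medianFilter)) {
    rate <- as.numeric(runmed(rate, medianFilter, endrule = "keep"))
  }
  new("RateTrace",
    times = grid, rate = as.numeric(rate), population = population,
    nNeurons = x@sizes[[population]], window = window, step = step
  )
})

#' @describeIn populationRate display method
#' @param object a `RateTrace`.
#' @export
setMethod("show", "RateTrace", function(object) {
  cat(sprintf(
    "RateTrace: population %s, %d points (window %g ms, step %g ms), peak %.1f Hz\n",
    object@population, length(object@times), object@window, object@step,
    if (length(object@rate)) max(object@rate) else 0
  ))
})

#' @describeIn populationRate rate trace as a data.frame
#' @param x a `RateTrace`.
#' @param row.names,optional ignored (S3 compatibility).
#' @param ... ignored.
#' @export
as.data.frame.RateTrace <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(time_ms = x@times, rate_hz = x@rate)
}

# first grid index from which `rate >= threshold` holds for `sustain`
# consecutive grid points, restricted to times strictly after `onset`
.sustainedCrossing <- function(trace, threshold, onset, sustain) {
  above <- trace@rate >= threshold & trace@times > onset
  if (sustain > 1) {
    run <- above
    for (k in seq_len(sustain - 1)) {
      run <- run & c(above[-seq_len(k)], rep(FALSE, k))
    }
    above <- run
  }
  which(above)[1]
}

#' Classify the decision of a trial from its two rate traces
#'
#' The winner is the first population whose rate reaches the decision
#' threshold (15 Hz by default) after stimulus onset and stays there for
#' `sustain` consecutive grid points; the decision (reaction) time is the
#' interval from stimulus onset to that crossing. If neither population
#' crosses before trial end the trial is undecided. When both cross in the
#' same window the tie is broken by the larger rate at the crossing, then
#' by label A, and the outcome is flagged.
#'
#' @param rateA,rateB [RateTrace-class] of populations A and B on a shared
#'   grid.
#' @param threshold decision threshold (Hz).
#' @param onset stimulus onset (ms).
#' @param coherence signed coherence of the trial (for the correctness
#'   label; positive favors B).
#' @param stimEnd stimulus end (ms), used for the persistence checks; NA to
#'   skip them.
#' @param sustain number of consecutive grid points required at or above
#'   threshold (guards against single-window noise).
#' @return a [TrialOutcome-class].
#' @export
classifyDecision <- function(rateA, rateB, threshold = 15, onset = 0,
                             coherence = NA_real_, stimEnd = NA_real_,
                             sustain = 2) {
  stopifnot(is(rateA, "RateTrace"), is(rateB, "RateTrace"))
  if (!isTRUE(all.equal(rateA@times, rateB@times))) {
    stop("the two rate traces must share a time grid")
  }
  ia <- .sustainedCrossing(rateA, threshold, onset, sustain)
  ib <- .sustainedCrossing(rateB, threshold, onset, sustain)
  ta <- if (is.na(ia)) Inf else rateA@times[ia]
  tb <- if (is.na(ib)) Inf else rateB@times[ib]
  tie <- FALSE
  if (is.infinite(ta) && is.infinite(tb)) {
    return(new("TrialOutcome",
      winner = "none", decisionTime = NA_real_, coherence = coherence,
      correct = NA, persisted = NA, delayRatio = NA_real_, tie = FALSE,
      threshold = threshold
    ))
  }
  if (ta == tb) {
    tie <- TRUE
    winner <- if (rateA@rate[ia] >= rateB@rate[ib]) "A" else "B"
  } else {
    winner <- if (ta < tb) "A" else "B"
  }
  tCross <- min(ta, tb)
  wTrace <- if (winner == "A") rateA else rateB
  lTrace <- if (winner == "A") rateB else rateA
  correct <- if (is.na(coherence) || coherence == 0) {
    NA
  } else if (coherence > 0) {
    winner == "B"
  } else {
    winner == "A"
  }
  persisted <- NA
  delayRatio <- NA_real_
  if (!is.na(stimEnd)) {
    delay <- wTrace@times > stimEnd
    if (any(delay)) {
      persisted <- all(wTrace@rate[delay] > lTrace@rate[delay])
      stimEpoch <- wTrace@times > onset & wTrace@times <= stimEnd
      peak <- if (any(stimEpoch)) max(wTrace@rate[stimEpoch]) else NA_real_
      tEnd <- max(wTrace@times)
      lastHalf <- wTrace@times > max(stimEnd, tEnd - 500)
      if (!is.na(peak) && peak > 0 && any(lastHalf)) {
        delayRatio <- mean(wTrace@rate[lastHalf]) / peak
      }
    }
  }
  new("TrialOutcome",
    winner = winner, decisionTime = tCross - onset, coherence = coherence,
    correct = correct, persisted = persisted, delayRatio = delayRatio,
    tie = tie, threshold = threshold
  )
}

#' @describeIn classifyDecision classify directly from a [SpikeTrains-class]
#'   using its stored protocol context.
#' @param x a `SpikeTrains`.
#' @param window,step,medianFilter passed to [populationRate()].
#' @export
classifyTrial <- function(x, threshold = 15, window = 50, step = 5,
                          medianFilter = NULL, sustain = 2) {
  stopifnot(is(x, "SpikeTrains"))
  rateA <- populationRate(x, "A", window = window, step = step,
    medianFilter = medianFilter)
  rateB <- populationRate(x, "B", window = window, step = step,
    medianFilter = medianFilter)
  onset <- if (is.na(x@stimOnset)) 0 else x@stimOnset
  classifyDecision(rateA, rateB,
    threshold = threshold, onset = onset,
    coherence = x@coherence, stimEnd = x@stimEnd, sustain = sustain
  )
}

#' @describeIn classifyDecision display method
#' @param object a `TrialOutcome`.
#' @export
setMethod("show", "TrialOutcome", function(object) {
  if (object@winner == "none") {
    cat("TrialOutcome: undecided\n")
  } else {
    cat(sprintf(
      "TrialOutcome: %s wins at %g ms%s%s%s\n", object@winner,
      object@decisionTime,
      if (isTRUE(object@correct)) " (correct)" else if (isFALSE(object@correct)) " (error)" else "",
      if (isTRUE(object@persisted)) ", persisted" else "",
      if (object@tie) ", tie-broken" else ""
    ))
  }
})

#' Decision-space trajectory
#'
#' The pair of population rates as an ordered trajectory, with the
#' perpendicular distance from the diagonal `|rateA - rateB| / sqrt(2)`
#' exposed for the random-walk-around-the-diagonal analysis: divergence
#' from the diagonal marks decision formation.
#'
#' @param rateA,rateB [RateTrace-class] on a shared grid.
#' @return data.frame with columns `time_ms`, `rateA`, `rateB`, `distance`.
#' @export
decisionSpace <- function(rateA, rateB) {
  stopifnot(is(rateA, "RateTrace"), is(rateB, "RateTrace"))
  if (!isTRUE(all.equal(rateA@times, rateB@times))) {
    stop("the two rate traces must share a time grid")
  }
  data.frame(
    time_ms = rateA@times, rateA = rateA@rate, rateB = rateB@rate,
    distance = abs(rateA@rate - rateB@rate) / sqrt(2)
  )
}

#' Weibull neurometric function
#'
#' `pct = 1 - 0.5 * exp(-(c / alpha) ^ beta)`: chance (0.5) at zero
#' coherence, saturating at 1; `alpha` is the coherence (percent) at which
#' performance reaches `1 - 0.5/e` (about 0.816).
#'
#' @param coherence coherence in percent, non-negative.
#' @param alpha scale (percent coherence), positive.
#' @param beta shape, positive.
#' @return fraction correct in `[0.5, 1]`.
#' @examples
#' weibullPercentCorrect(9.2, 9.2, 1.5) # 1 - 0.5/e
#' @export
weibullPercentCorrect <- function(coherence, alpha, beta) {
  stopifnot(all(coherence >= 0), alpha > 0)
  1 - 0.5 * exp(-(coherence / alpha)^beta)
}

#' Fit the Weibull neurometric function
#'
#' Least-squares fit of [weibullPercentCorrect()] to percent-correct versus
#' coherence (percent units), via Levenberg-Marquardt. Degenerate data (all
#' at chance, all saturated, or too few levels to identify the shape) yield
#' a flagged, non-converged fit instead of an error.
#'
#' @param coherences coherence levels in percent (absolute values).
#' @param pctCorrect fraction correct per level, in `[0, 1]`.
#' @param start optional named list with starting `alpha` and `beta`.
#' @return a [NeurometricFit-class].
#' @examples
#' cc <- c(3.2, 6.4, 12.8, 25.6, 51.2)
#' fitWeibull(cc, weibullPercentCorrect(cc, 9.2, 1.5))
#' @export
fitWeibull <- function(coherences, pctCorrect, start = NULL) {
  stopifnot(length(coherences) == length(pctCorrect))
  keep <- is.finite(coherences) & is.finite(pctCorrect)
  cc <- abs(coherences[keep])
  pc <- pctCorrect[keep]
  failed <- function() {
    new("NeurometricFit",
      alpha = NA_real_, beta = NA_real_, coherences = cc, pctCorrect = pc,
      residuals = rep(NA_real_, length(cc)), converged = FALSE
    )
  }
  if (length(cc) < 3) return(failed())
  # degenerate: no usable slope between chance and saturation
  if (all(pc <= 0.5 + 1e-12) || all(pc >= 1 - 1e-12) || sd(pc) < 1e-12) {
    return(failed())
  }
  if (is.null(start)) {
    iMid <- which.min(abs(pc - (1 - 0.5 * exp(-1))))
    start <- list(alpha = max(cc[iMid], 1e-3), beta = 1.5)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      pc ~ 1 - 0.5 * exp(-(cc / alpha)^beta),
      start = start,
      lower = c(alpha = 1e-6, beta = 1e-6),
      upper = c(alpha = 1e4, beta = 50),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
        ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  est <- coef(fit)
  new("NeurometricFit",
    alpha = unname(est["alpha"]), beta = unname(est["beta"]),
    coherences = cc, pctCorrect = pc,
    residuals = as.numeric(resid(fit)), converged = TRUE
  )
}

#' @describeIn fitWeibull display method
#' @param object a `NeurometricFit`.
#' @export
setMethod("show", "NeurometricFit", function(object) {
  if (!object@converged) {
    cat("NeurometricFit: not converged (degenerate data)\n")
  } else {
    cat(sprintf(
      "NeurometricFit: alpha = %.2f%% coherence, beta = %.2f (RMS residual %.3g)\n",
      object@alpha, object@beta, sqrt(mean(object@residuals^2))
    ))
  }
})

#' Outcome-conditioned mean response of a population
#'
#' Splits the trials of a batch into the four outcome cells used to study
#' correct and error responses of population B (or A): winner B or A,
#' crossed with whether the stimulus favored B. Returns the across-trial
#' mean rate trace of the chosen population per coherence level and cell.
#' Zero-coherence trials carry no correct/error label and are rejected.
#'
#' @param batch result of [runBatch()] run with `keepRates = TRUE`.
#' @param population population whose response is averaged (default "B").
#' @return list with `cells` (data.frame: coherence_pct, cell, nTrials) and
#'   `traces` (named list of mean-trace data.frames per
#'   coherence/cell combination). Cells are `winPreferred` (correct win),
#'   `winNonPreferred` (error win), `losePreferred` (error loss),
#'   `loseNonPreferred` (correct loss).
#' @export
conditionOnOutcome <- function(batch, population = "B") {
  if (is.null(batch$rates)) {
    stop("the batch must be run with keepRates = TRUE")
  }
  summ <- batch$summary
  if (any(summ$coherence_pct == 0)) {
    stop("correct/error conditioning is undefined at zero coherence; ",
      "rerun the batch with |coherence| > 0")
  }
  decided <- summ$winner != "none"
  cellOf <- function(winner, coh) {
    preferred <- if (population == "B") coh > 0 else coh < 0
    win <- winner == population
    if (win && preferred) "winPreferred"
    else if (win && !preferred) "winNonPreferred"
    else if (!win && preferred) "losePreferred"
    else "loseNonPreferred"
  }
  cells <- data.frame()
  traces <- list()
  for (cohPct in sort(unique(abs(summ$coherence_pct)))) {
    sel <- which(decided & abs(summ$coherence_pct) == cohPct)
    if (!length(sel)) next
    cellLabels <- vapply(
      sel,
      function(i) cellOf(summ$winner[i], summ$coherence_pct[i]),
      character(1)
    )
    for (cell in c("winPreferred", "winNonPreferred", "losePreferred",
      "loseNonPreferred")) {
      idx <- sel[cellLabels == cell]
      if (!length(idx)) {
        warning(sprintf(
          "no trials in cell %s at %.1f%% coherence; trace omitted",
          cell, cohPct
        ))
        next
      }
      mat <- vapply(
        idx,
        function(i) batch$rates[[i]][[population]]@rate,
        numeric(length(batch$rates[[idx[1]]][[population]]@rate))
      )
      key <- sprintf("c%.1f_%s", cohPct, cell)
      traces[[key]] <- data.frame(
        time_ms = batch$rates[[idx[1]]][[population]]@times,
        rate_hz = rowMeans(mat)
      )
      cells <- rbind(cells, data.frame(
        coherence_pct = cohPct, cell = cell, nTrials = length(idx)
      ))
    }
  }
  list(cells = cells, traces = traces)
}
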