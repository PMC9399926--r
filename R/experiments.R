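#' @include analysis.R
NULL

# unique per-trial seeds derived from one master seed
.trialSeeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a batch of independent trials
#'
#' One independent trial per (coherence, replicate): each trial rebuilds
#' its connectivity, background rates and stimulus from its own seed, all
#' derived deterministically from `seed`, so the whole batch is a pure
#' function of `(config, coherences, nTrials, seed, protocol)`.
#'
#' @param config a [NetworkConfig-class].
#' @param coherences signed coherence levels in percent (e.g.
#'   `c(-51.2, -25.6, ..., 51.2)`).
#' @param nTrials trials per coherence level.
#' @param seed master seed of the batch.
#' @param protocol base [TrialProtocol-class]; its coherence is replaced
#'   per trial.
#' @param threshold,window,step,medianFilter,sustain decision-readout
#'   settings, see [classifyTrial()].
#' @param keepRates keep the per-trial A/B rate traces (needed by
#'   [conditionOnOutcome()]); off by default to bound memory.
#' @return list with `summary` (data.frame: trial, coherence_pct, seed,
#'   winner, correct, decision_time_ms, persisted, delay_ratio, tie) and
#'   `rates` (list of per-trial traces, or NULL).
#' @examples
#' \donttest{
#' cfg <- defaultConfig(scale = 0.5)
#' b <- runBatch(cfg, coherences = c(-51.2, 51.2), nTrials = 2, seed = 1)
#' b$summary
#' }
#' @export
runBatch <- function(config, coherences, nTrials, seed,
                     protocol = trialProtocol(),
                     threshold = 15, window = 50, step = 5,
                     medianFilter = NULL, sustain = 2,
                     keepRates = FALSE) {
  stopifnot(is(config, "NetworkConfig"), nTrials >= 0)
  conditions <- expand.grid(
    rep = seq_len(nTrials), coherence_pct = coherences
  )
  nTotal <- nrow(conditions)
  seeds <- if (nTotal) .trialSeeds(seed, nTotal) else integer(0)
  rows <- vector("list", nTotal)
  rates <- if (keepRates) vector("list", nTotal) else NULL
  for (i in seq_len(nTotal)) {
    cohPct <- conditions$coherence_pct[i]
    prot <- protocol
    prot@coherence <- cohPct / 100
    validObject(prot)
    spk <- tryCatch(
      runTrial(config, prot, seeds[i]),
      error = function(e) e
    )
    if (inherits(spk, "error")) {
      rows[[i]] <- data.frame(
        trial = i, coherence_pct = cohPct, seed = seeds[i],
        winner = NA_character_, correct = NA, decision_time_ms = NA_real_,
        persisted = NA, delay_ratio = NA_real_, tie = NA,
        error = conditionMessage(spk)
      )
      next
    }
    out <- classifyTrial(spk,
      threshold = threshold, window = window,
      step = step, medianFilter = medianFilter, sustain = sustain
    )
    rows[[i]] <- data.frame(
      trial = i, coherence_pct = cohPct, seed = seeds[i],
      winner = out@winner, correct = out@correct,
      decision_time_ms = out@decisionTime, persisted = out@persisted,
      delay_ratio = out@delayRatio, tie = out@tie, error = NA_character_
    )
    if (keepRates) {
      rates[[i]] <- list(
        A = populationRate(spk, "A", window = window, step = step),
        B = populationRate(spk, "B", window = window, step = step)
      )
    }
  }
  list(summary = do.call(rbind, rows), rates = rates)
}

#' Neurometric curve from a batch summary
#'
#' Percent correct per absolute coherence level for one population's
#' preferred direction, among decided trials.
#'
#' @param summary the `summary` data.frame of [runBatch()].
#' @param population `"A"` (its preferred direction is negative coherence)
#'   or `"B"` (positive).
#' @return data.frame with columns `coherence_pct`, `n`, `nDecided`,
#'   `pctCorrect`.
#' @export
neurometricCurve <- function(summary, population = c("A", "B")) {
  population <- match.arg(population)
  sel <- if (population == "A") {
    summary$coherence_pct < 0
  } else {
    summary$coherence_pct > 0
  }
  s <- summary[sel & is.na(summary$error), ]
  out <- do.call(rbind, lapply(split(s, abs(s$coherence_pct)), function(g) {
    dec <- g$winner != "none"
    data.frame(
      coherence_pct = abs(g$coherence_pct[1]),
      n = nrow(g),
      nDecided = sum(dec),
      pctCorrect = if (any(dec)) mean(g$winner[dec] == population) else NA_real_
    )
  }))
  rownames(out) <- NULL
  out[order(out$coherence_pct), ]
}

#' Zero-coherence "coin toss" experiment
#'
#' Presents a fully ambiguous stimulus (coherence 0) and reports how often
#' each population wins. With `sigma0 = 0` (default here) the stimulus is
#' noiseless, so the only stochasticity left is the background Poisson
#' noise and the connectivity draw -- the mode used to show that the
#' decision variability originates in the background noise rather than in
#' the stimulus fluctuations.
#'
#' @param config a [NetworkConfig-class]; its `sigma0` is overridden by the
#'   `sigma0` argument.
#' @param nTrials number of trials.
#' @param seed master seed.
#' @param sigma0 stimulus fluctuation SD (Hz); 0 removes stimulus noise.
#' @param protocol base protocol (coherence forced to 0).
#' @param ... decision-readout settings passed to [runBatch()].
#' @return list with `pctA`, `pctB` (percent of decided trials won by each
#'   population), `nDecided`, `nUndecided` and the full `summary`.
#' @export
coinToss <- function(config, nTrials, seed, sigma0 = 0,
                     protocol = trialProtocol(), ...) {
  cfg <- config
  cfg@sigma0 <- sigma0
  batch <- runBatch(cfg,
    coherences = 0, nTrials = nTrials, seed = seed,
    protocol = protocol, ...
  )
  s <- batch$summary
  decided <- !is.na(s$winner) & s$winner != "none"
  nDec <- sum(decided)
  list(
    pctA = if (nDec) 100 * sum(s$winner[decided] == "A") / nDec else NA_real_,
    pctB = if (nDec) 100 * sum(s$winner[decided] == "B") / nDec else NA_real_,
    nDecided = nDec,
    nUndecided = sum(!decided),
    summary = s
  )
}

#' Stimulus-duration sweep
#'
#' Repeats a fixed-coherence batch while shortening the stimulus epoch,
#' reporting the fraction of trials that reach a decision and, among
#' those, the fraction whose winner persists through the post-stimulus
#' delay. Shorter stimuli leave the network less time to accumulate
#' evidence, reducing the decided fraction.
#'
#' @param config a [NetworkConfig-class].
#' @param durations stimulus durations (ms), e.g. `c(500, 700, 900, 1000)`.
#' @param coherence signed coherence in percent.
#' @param nTrials trials per duration.
#' @param seed master seed (shared across durations, so per-trial seeds are
#'   paired between conditions).
#' @param tPre,tPost baseline and delay durations (ms).
#' @param ... decision-readout settings passed to [runBatch()].
#' @return data.frame with one row per duration: `duration_ms`, `n`,
#'   `fracDecided`, `fracPersistent`, `medianRT_ms`.
#' @export
durationSweep <- function(config, durations = c(500, 700, 900, 1000),
                          coherence = -12.8, nTrials, seed,
                          tPre = 500, tPost = 1500, ...) {
  out <- lapply(durations, function(d) {
    batch <- runBatch(config,
      coherences = coherence, nTrials = nTrials,
      seed = seed,
      protocol = trialProtocol(tPre = tPre, tStim = d, tPost = tPost), ...
    )
    s <- batch$summary
    decided <- !is.na(s$winner) & s$winner != "none"
    data.frame(
      duration_ms = d, n = nrow(s),
      fracDecided = mean(decided),
      fracPersistent = if (any(decided)) {
        mean(s$persisted[decided], na.rm = TRUE)
      } else {
        NA_real_
      },
      medianRT_ms = if (any(decided)) {
        median(s$decision_time_ms[decided])
      } else {
        NA_real_
      }
    )
  })
  do.call(rbind, out)
}

#' Decision-reversal sweeps
#'
#' Reverses the stimulus mid-trial and reports the choice percentages per
#' condition. Two standard protocols are covered: varying the reversal
#' *time* (coherence `cBefore` switched to `cAfter` at each of
#' `reversalTimes`), and varying the reversed *intensity* (fixed switch
#' time, several `cAfter` values); both are expressed through the argument
#' vectors, with scalar arguments recycled.
#'
#' @param config a [NetworkConfig-class].
#' @param cBefore,cAfter coherences in percent before and after the switch.
#' @param reversalTimes switch times (ms from stimulus onset).
#' @param tStim total stimulus duration (ms); for a reversal at 1000 ms
#'   followed by 1000 ms of reversed stimulus pass `tStim = 2000`.
#' @param nTrials trials per condition.
#' @param seed master seed, shared across conditions (paired trials).
#' @param tPre,tPost baseline and delay durations (ms).
#' @param ... decision-readout settings passed to [runBatch()].
#' @return data.frame with one row per condition: `cBefore_pct`,
#'   `cAfter_pct`, `reversal_ms`, `n`, `nDecided`, `pctA`, `pctB`.
#' @export
reversalSweep <- function(config, cBefore = -6.4, cAfter = 6.4,
                          reversalTimes = c(300, 500, 700, 900, 1000),
                          tStim = 1000, nTrials, seed,
                          tPre = 500, tPost = 1500, ...) {
  conds <- data.frame(
    cBefore = cBefore, cAfter = cAfter, tRev = reversalTimes
  )
  out <- lapply(seq_len(nrow(conds)), function(k) {
    prot <- trialProtocol(
      coherence = conds$cBefore[k] / 100, tPre = tPre, tStim = tStim,
      tPost = tPost,
      reversalTime = conds$tRev[k], coherenceAfter = conds$cAfter[k] / 100
    )
    batch <- runBatch(config,
      coherences = conds$cBefore[k], nTrials = nTrials, seed = seed,
      protocol = prot, ...
    )
    # runBatch rewrites the protocol coherence from `coherences`; the
    # reversal fields are preserved
    s <- batch$summary
    decided <- !is.na(s$winner) & s$winner != "none"
    nDec <- sum(decided)
    data.frame(
      cBefore_pct = conds$cBefore[k], cAfter_pct = conds$cAfter[k],
      reversal_ms = conds$tRev[k], n = nrow(s), nDecided = nDec,
      pctA = if (nDec) 100 * sum(s$winner[decided] == "A") / nDec else NA_real_,
      pctB = if (nDec) 100 * sum(s$winner[decided] == "B") / nDec else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Mechanism ablations with seed-matched controls
#'
#' Runs an altered network side by side with the unaltered control on the
#' same per-trial seeds, so any difference is attributable to the single
#' overridden mechanism:
#'
#' * `reduced_w_plus`: the potentiation of the within-population recurrent
#'   synapses is lowered from 1.7 to `wPlusAblated` on both receptor
#'   components — the AMPA weight goes to `wPlusAblated` and the NMDA
#'   multiplier is rescaled proportionally, `wNMDA * wPlusAblated / wPlus`
#'   (4.25 to 3.5 at the defaults). The excitatory-inhibitory pathway is
#'   left at control strength: the ablation probes the recurrent-excitation
#'   mechanism, not the inhibition recruitment. Expected signature: no
#'   categorical decision at low coherence; winner-take-all still forms
#'   under a strong stimulus but the winner's activity decays once the
#'   stimulus ends (working memory destroyed).
#' * `fast_nmda`: the NMDA channel's time constant is set equal to the
#'   AMPA one (2 ms), removing the slow reverberation. Expected signature:
#'   no ramp to the decision threshold and no suppression of the losing
#'   population, even at 51.2 percent coherence.
#'
#' @param kind `"reduced_w_plus"` or `"fast_nmda"`.
#' @param config base [NetworkConfig-class].
#' @param coherences signed coherence levels in percent.
#' @param nTrials trials per coherence.
#' @param seed master seed (shared between control and ablated runs).
#' @param wPlusAblated reduced potentiation for `reduced_w_plus`.
#' @param ... decision-readout settings passed to [runBatch()].
#' @return list with `kind`, `control` and `ablated` batch summaries, and
#'   `configAblated`.
#' @export
ablationRun <- function(kind = c("reduced_w_plus", "fast_nmda"), config,
                        coherences, nTrials, seed, wPlusAblated = 1.4,
                        ...) {
  kind <- match.arg(kind)
  cfgAbl <- config
  if (kind == "reduced_w_plus") {
    cfgAbl@wNMDA <- config@wNMDA * wPlusAblated / config@wPlus
    cfgAbl@wWithinAMPA <- wPlusAblated
  } else {
    cfgAbl@ports$tauSyn[cfgAbl@ports$label == "NMDA"] <-
      cfgAbl@ports$tauSyn[cfgAbl@ports$label == "AMPA"]
  }
  validObject(cfgAbl)
  control <- runBatch(config,
    coherences = coherences, nTrials = nTrials,
    seed = seed, ...
  )
  ablated <- runBatch(cfgAbl,
    coherences = coherences, nTrials = nTrials,
    seed = seed, ...
  )
  list(
    kind = kind, control = control$summary, ablated = ablated$summary,
    configAblated = cfgAbl
  )
}
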