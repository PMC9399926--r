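# Rate estimation, decision classification, decision space, Weibull fits.

emptyTrains <- function(sizes = c(A = 10L, B = 10L, I = 5L), dur = 1000) {
  new("SpikeTrains",
    time = numeric(0), id = integer(0),
    population = factor(character(0), levels = c("A", "B", "I")),
    sizes = structure(as.integer(sizes), names = c("A", "B", "I")),
    duration = dur, stimOnset = NA_real_, stimEnd = NA_real_,
    coherence = NA_real_
  )
}

makeTrace <- function(times, rate, pop = "A", n = 10L) {
  new("RateTrace",
    times = times, rate = rate, population = pop, nNeurons = n,
    window = 50, step = 5
  )
}

test_that("population rate recovers homogeneous Poisson activity", {
  empty <- populationRate(emptyTrains(), "A")
  expect_true(all(empty@rate == 0))
  expect_error(populationRate(emptyTrains(), "X"), "unknown population")
  # 800 neurons at 20 Hz for 1 s
  set.seed(71)
  trains <- lapply(1:800, function(i) generatePoissonSpikes(20, 0, 1000))
  tt <- unlist(trains)
  id <- rep(seq_along(trains), lengths(trains))
  ord <- order(tt)
  spk <- new("SpikeTrains",
    time = tt[ord], id = as.integer(id[ord]),
    population = factor(rep("A", length(tt)), levels = c("A", "B", "I")),
    sizes = c(A = 800L, B = 1L, I = 1L), duration = 1000,
    stimOnset = NA_real_, stimEnd = NA_real_, coherence = NA_real_
  )
  tr <- populationRate(spk, "A")
  steady <- tr@rate[tr@times >= 50]
  expect_lt(abs(mean(steady) - 20) / 20, 0.05)
  # a single spike in one window contributes 1/(n * window)
  one <- new("SpikeTrains",
    time = 500, id = 3L,
    population = factor("B", levels = c("A", "B", "I")),
    sizes = c(A = 10L, B = 10L, I = 5L), duration = 1000,
    stimOnset = NA_real_, stimEnd = NA_real_, coherence = NA_real_
  )
  trB <- populationRate(one, "B", window = 50, step = 5)
  expect_equal(max(trB@rate), 1 / (10 * 50) * 1000)
})

test_that("decision classification follows the sustained threshold rule", {
  grid <- seq(5, 3000, by = 5)
  flat <- rep(2, length(grid))
  ramp <- ifelse(grid >= 1150, 20, ifelse(grid >= 1100, 16, 2))
  out <- classifyDecision(
    makeTrace(grid, ramp, "A"), makeTrace(grid, flat, "B"),
    threshold = 15, onset = 500, coherence = -0.128, stimEnd = 1500
  )
  expect_equal(out@winner, "A")
  expect_equal(out@decisionTime, 600) # first crossing at 1100 ms
  expect_true(out@correct)
  expect_true(out@persisted)
  # neither crossing: undecided
  und <- classifyDecision(
    makeTrace(grid, flat, "A"), makeTrace(grid, flat, "B"),
    threshold = 15, onset = 500
  )
  expect_equal(und@winner, "none")
  expect_true(is.na(und@decisionTime))
  # a single-window blip is rejected by the sustained rule
  blip <- flat
  blip[grid == 1100] <- 30
  outBlip <- classifyDecision(
    makeTrace(grid, blip, "A"), makeTrace(grid, flat, "B"),
    threshold = 15, onset = 500, sustain = 2
  )
  expect_equal(outBlip@winner, "none")
  # simultaneous crossing: tie broken by the larger rate, flagged
  rampB <- ifelse(grid >= 1100, 25, 2)
  tie <- classifyDecision(
    makeTrace(grid, ramp, "A"), makeTrace(grid, rampB, "B"),
    threshold = 15, onset = 500
  )
  expect_equal(tie@winner, "B")
  expect_true(tie@tie)
})

test_that("decision space exposes the distance from the diagonal", {
  grid <- seq(5, 100, by = 5)
  a <- makeTrace(grid, rep(12, length(grid)), "A")
  b <- makeTrace(grid, rep(2, length(grid)), "B")
  ds <- decisionSpace(a, b)
  expect_equal(ds$distance, rep(10 / sqrt(2), length(grid)))
  dsSame <- decisionSpace(a, a)
  expect_true(all(dsSame$distance == 0))
})

test_that("the Weibull neurometric function has its defining landmarks", {
  expect_equal(weibullPercentCorrect(0, 9.2, 1.5), 0.5)
  expect_equal(weibullPercentCorrect(1e9, 9.2, 1.5), 1)
  expect_equal(
    weibullPercentCorrect(9.2, 9.2, 1.5), 1 - 0.5 * exp(-1)
  )
})

test_that("noiseless Weibull data are recovered to high precision", {
  cc <- c(3.2, 6.4, 12.8, 25.6, 51.2)
  fit <- fitWeibull(cc, weibullPercentCorrect(cc, 9.2, 1.5))
  expect_true(fit@converged)
  expect_equal(fit@alpha, 9.2, tolerance = 1e-6)
  expect_equal(fit@beta, 1.5, tolerance = 1e-6)
})

test_that("the Weibull fit is robust to binomial sampling noise", {
  cc <- c(3.2, 6.4, 12.8, 25.6, 51.2)
  truth <- weibullPercentCorrect(cc, 9.2, 1.5)
  set.seed(81)
  alphas <- replicate(100, {
    pc <- rbinom(length(cc), 200, truth) / 200
    fitWeibull(cc, pc)@alpha
  })
  expect_lt(abs(median(alphas, na.rm = TRUE) - 9.2) / 9.2, 0.2)
})

test_that("degenerate neurometric data are flagged, not fatal", {
  cc <- c(3.2, 6.4, 12.8, 25.6, 51.2)
  expect_false(fitWeibull(cc, rep(0.5, 5))@converged)
  expect_false(fitWeibull(cc, rep(1, 5))@converged)
  expect_false(fitWeibull(cc[1:2], c(0.6, 0.9))@converged)
})

test_that("outcome conditioning splits trials into the four cells", {
  grid <- seq(5, 3000, by = 5)
  mkRates <- function(rB) {
    list(
      A = makeTrace(grid, rep(2, length(grid)), "A"),
      B = makeTrace(grid, rep(rB, length(grid)), "B")
    )
  }
  summary <- data.frame(
    trial = 1:4, coherence_pct = c(12.8, 12.8, -12.8, -12.8), seed = 1:4,
    winner = c("B", "A", "B", "A"),
    correct = c(TRUE, FALSE, FALSE, TRUE),
    decision_time_ms = c(600, 800, 700, 650), persisted = TRUE,
    delay_ratio = 0.9, tie = FALSE, error = NA_character_
  )
  batch <- list(summary = summary, rates = lapply(c(20, 3, 25, 2), mkRates))
  cond <- conditionOnOutcome(batch, population = "B")
  expect_setequal(
    cond$cells$cell,
    c("winPreferred", "loseNonPreferred", "winNonPreferred", "losePreferred")
  )
  expect_equal(
    cond$traces[["c12.8_winPreferred"]]$rate_hz,
    rep(20, length(grid))
  )
  # zero coherence has no correct/error split
  s0 <- summary
  s0$coherence_pct <- 0
  expect_error(
    conditionOnOutcome(list(summary = s0, rates = batch$rates)),
    "zero coherence"
  )
})
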