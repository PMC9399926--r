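# Batch contracts, ablation overrides, and the text I/O round trips.
# Dynamics-level properties of the experiments live in the acceptance
# suite; here the tiny networks only exercise the plumbing.

tinyConfig <- function(...) defaultConfig(scale = 0.1, ...)
tinyProtocol <- trialProtocol(0, tPre = 100, tStim = 200, tPost = 100)

test_that("batches are deterministic and rerunnable", {
  cfg <- tinyConfig()
  b1 <- runBatch(cfg, c(-51.2, 51.2), nTrials = 1, seed = 5,
    protocol = tinyProtocol)
  b2 <- runBatch(cfg, c(-51.2, 51.2), nTrials = 1, seed = 5,
    protocol = tinyProtocol)
  expect_identical(b1$summary, b2$summary)
  expect_equal(nrow(b1$summary), 2)
  expect_equal(sort(unique(b1$summary$coherence_pct)), c(-51.2, 51.2))
  expect_false(any(duplicated(b1$summary$seed)))
})

test_that("coinToss partitions decided trials and survives n = 0", {
  cfg <- tinyConfig()
  empty <- coinToss(cfg, nTrials = 0, seed = 1)
  expect_true(is.na(empty$pctA))
  expect_equal(empty$nDecided + empty$nUndecided, 0)
  ct <- coinToss(cfg, nTrials = 3, seed = 2, protocol = tinyProtocol)
  expect_equal(nrow(ct$summary), 3)
  if (ct$nDecided > 0) {
    expect_equal(ct$pctA + ct$pctB, 100)
  }
  # the sigma0 override reaches the stimulus model
  expect_equal(unique(ct$summary$coherence_pct), 0)
})

test_that("ablation overrides touch only the declared mechanism", {
  cfg <- defaultConfig(scale = 0.5)
  ab <- ablationRun("reduced_w_plus", cfg,
    coherences = 51.2, nTrials = 0, seed = 1
  )
  expect_equal(ab$configAblated@wWithinAMPA, 1.4)
  expect_equal(ab$configAblated@wNMDA, 4.25 * 1.4 / 1.7)
  expect_equal(ab$configAblated@wPlus, cfg@wPlus) # E<->I untouched
  expect_equal(ab$configAblated@ports, cfg@ports)
  expect_equal(ab$configAblated@epsEE, cfg@epsEE)
  fast <- ablationRun("fast_nmda", cfg,
    coherences = 51.2, nTrials = 0, seed = 1
  )
  expect_equal(
    fast$configAblated@ports$tauSyn[fast$configAblated@ports$label == "NMDA"],
    cfg@ports$tauSyn[cfg@ports$label == "AMPA"]
  )
  expect_equal(fast$configAblated@wPlus, cfg@wPlus)
})

test_that("a duration-zero stimulus is a protocol without stimulus epoch", {
  cfg <- tinyConfig()
  sw <- durationSweep(cfg,
    durations = 0, coherence = -12.8, nTrials = 1, seed = 3,
    tPre = 100, tPost = 100
  )
  expect_equal(sw$duration_ms, 0)
  expect_true(sw$fracDecided %in% c(0, 1)) # classified, not crashed
})

test_that("spike records round-trip losslessly through TSV", {
  cfg <- tinyConfig()
  spk <- runTrial(cfg, trialProtocol(0.512, tPre = 100, tStim = 300,
    tPost = 100), seed = 11)
  path <- tempfile(fileext = ".tsv")
  writeSpikes(spk, path)
  back <- readSpikes(path)
  expect_equal(back@time, round(spk@time, 3))
  expect_identical(back@id, spk@id)
  expect_identical(back@population, spk@population)
  expect_identical(back@sizes, spk@sizes)
  expect_equal(back@duration, spk@duration)
  expect_equal(back@coherence, spk@coherence)
  # an empty record round-trips too
  silent <- new("SpikeTrains",
    time = numeric(0), id = integer(0),
    population = factor(character(0), levels = c("A", "B", "I")),
    sizes = c(A = 5L, B = 5L, I = 2L), duration = 100,
    stimOnset = NA_real_, stimEnd = NA_real_, coherence = NA_real_
  )
  p2 <- tempfile(fileext = ".tsv")
  writeSpikes(silent, p2)
  expect_length(readSpikes(p2)@time, 0)
})

test_that("trial summaries round-trip through CSV", {
  cfg <- tinyConfig()
  b <- runBatch(cfg, 0, nTrials = 2, seed = 7, protocol = tinyProtocol)
  path <- tempfile(fileext = ".csv")
  writeTrialSummary(b$summary, path)
  back <- readTrialSummary(path)
  expect_equal(back$winner, b$summary$winner)
  expect_equal(
    as.numeric(back$decision_time_ms), b$summary$decision_time_ms
  )
})

test_that("configurations round-trip through YAML and reject unknown keys", {
  cfg <- defaultConfig(scale = 0.5, wPlus = 1.4, sigma0 = 0)
  path <- tempfile(fileext = ".yaml")
  writeNetworkConfig(cfg, path)
  back <- readNetworkConfig(path)
  expect_equal(back@wPlus, 1.4)
  expect_equal(back@sigma0, 0)
  expect_equal(back@sizes, cfg@sizes)
  expect_equal(back@epsEE, cfg@epsEE)
  expect_equal(back@ports, cfg@ports)
  # an empty file gives the full defaults
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(readNetworkConfig(empty)@wNMDA, 4.25)
  # a single override leaves everything else at defaults
  one <- tempfile(fileext = ".yaml")
  writeLines("weights:\n  w_plus: 1.4", one)
  cfgOne <- readNetworkConfig(one)
  expect_equal(cfgOne@wPlus, 1.4)
  expect_equal(cfgOne@wNMDA, 4.25)
  # unknown keys and invalid invariants are named in the failure
  badKey <- tempfile(fileext = ".yaml")
  writeLines("weights:\n  w_bogus: 2", badKey)
  expect_error(readNetworkConfig(badKey), "w_bogus")
  badTau <- tempfile(fileext = ".yaml")
  writeLines("ports:\n  NMDA:\n    tau_syn: -1", badTau)
  expect_error(readNetworkConfig(badTau), "tauSyn")
})

test_that("the network audit serializes to JSON", {
  net <- buildNetwork(defaultConfig(scale = 0.1), seed = 9)
  path <- tempfile(fileext = ".json")
  writeNetworkAudit(net, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$sizes$A, 80)
  expect_equal(length(parsed$groups), nrow(net@audit))
})

test_that("a run manifest captures what reproduces the run", {
  cfg <- tinyConfig()
  man <- runManifest(cfg, seed = 77, outputs = "x.tsv")
  expect_equal(man$master_seed, 77L)
  expect_equal(unlist(man$stream_seeds), deriveSeeds(77),
    ignore_attr = FALSE
  )
  # digest is stable for equal configurations, sensitive to changes
  expect_identical(man$config_digest, runManifest(cfg, 1)$config_digest)
  cfg2 <- tinyConfig(wPlus = 1.4)
  expect_false(identical(
    man$config_digest, runManifest(cfg2, 1)$config_digest
  ))
  # round trip and replay: same config + manifest seed => same spikes
  path <- tempfile(fileext = ".json")
  writeRunManifest(man, path)
  back <- readRunManifest(path)
  expect_equal(back$master_seed, 77)
  s1 <- runTrial(cfg, tinyProtocol, back$master_seed)
  s2 <- runTrial(cfg, tinyProtocol, 77)
  expect_identical(s1@time, s2@time)
})
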