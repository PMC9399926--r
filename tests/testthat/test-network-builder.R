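# Structure of the built network: sizes, projection table, weights, signs.

test_that("the default configuration reproduces the standard parameter set", {
  cfg <- defaultConfig()
  expect_equal(unname(populations(cfg)), c(800, 800, 400))
  expect_equal(cfg@wNMDA, 4.25)
  expect_equal(cfg@ports$tauSyn[cfg@ports$label == "NMDA"], 100)
  expect_equal(cfg@noiseExc, c(7719, 38))
  expect_equal(cfg@noiseInh, c(5789, 28))
  expect_equal(cfg@mu0, 772)
  expect_error(defaultConfig(bogusKnob = 1), "unknown configuration")
  expect_error(defaultConfig(J = -1), "J must be positive")
})

test_that("the projection table carries the standard weight multipliers", {
  tab <- projectionTable(defaultConfig())
  g <- function(s, t, p) tab[tab$source == s & tab$target == t & tab$port == p, ]
  expect_equal(g("A", "A", "NMDA")$w, 4.25)
  expect_equal(g("A", "A", "AMPA")$w, 1.7)
  expect_equal(g("A", "B", "AMPA")$w, 0.8)
  expect_equal(g("A", "B", "NMDA")$w, 0.8)
  expect_equal(g("A", "I", "AMPA")$w, 1.7)
  expect_equal(g("A", "I", "NMDA")$w, 1.7)
  # every excitatory projection carries both receptor components
  ee <- tab[tab$source %in% c("A", "B") & tab$target %in% c("A", "B", "I") &
    !tab$generator, ]
  expect_true(all(table(ee$source, ee$target) == 2))
  # generator wiring: noise to all three populations, stimulus per side
  gen <- tab[tab$generator, ]
  expect_setequal(gen$target[gen$source == "noise"], c("A", "B", "I"))
  expect_equal(gen$port[gen$source %in% c("stimA", "stimB")], c("AMPA", "AMPA"))
  # disabling the within-population AMPA potentiation switches that entry
  tab2 <- projectionTable(defaultConfig(potentiateWithinAMPA = FALSE))
  expect_equal(
    tab2[tab2$source == "A" & tab2$target == "A" & tab2$port == "AMPA", "w"],
    1
  )
})

test_that("built networks have the right sizes, scaling preserves the 2:2:1 ratio", {
  net <- buildNetwork(defaultConfig(), seed = 1)
  expect_equal(nNeurons(net), 2000)
  expect_equal(unname(populations(net)), c(800, 800, 400))
  netHalf <- buildNetwork(defaultConfig(scale = 0.5), seed = 1)
  expect_equal(nNeurons(netHalf), 1000)
  expect_equal(unname(populations(netHalf)), c(400, 400, 200))
  # epsilon rescaling preserves expected in-degrees across scales
  cfg1 <- defaultConfig(scale = 1)
  cfg2 <- defaultConfig(scale = 0.5)
  expect_equal(cfg1@epsEE * cfg1@sizes["A"], cfg2@epsEE * cfg2@sizes["A"])
  expect_equal(cfg1@epsIE * cfg1@sizes["I"], cfg2@epsIE * cfg2@sizes["I"])
})

test_that("realized connection counts match the Bernoulli expectation", {
  cfg <- defaultConfig(scale = 0.5, epsEE = 0.1)
  set.seed(41)
  net <- buildNetwork(cfg)
  aud <- net@audit
  withinA <- aud[aud$source == "A" & aud$target == "A" & aud$port == "AMPA", ]
  nExp <- 400 * 399 * 0.1
  expect_lt(
    abs(withinA$nConnections - nExp),
    4 * sqrt(400 * 399 * 0.1 * 0.9)
  )
})

test_that("GABA amplitudes hyperpolarize and all others depolarize", {
  net <- buildNetwork(defaultConfig(scale = 0.25), seed = 2)
  gabaIdx <- which(net@config@ports$label == "GABA") - 1L
  expect_true(all(net@connAmp[net@connPort == gabaIdx] < 0))
  expect_true(all(net@connAmp[net@connPort != gabaIdx] > 0))
  # no autapses anywhere
  expect_true(all(net@connSrc != net@connTgt))
})

test_that("the audit is structurally identical for any seed and scale", {
  a1 <- buildNetwork(defaultConfig(scale = 0.25), seed = 1)@audit
  a2 <- buildNetwork(defaultConfig(scale = 0.25), seed = 77)@audit
  expect_identical(
    a1[c("source", "target", "port", "epsilon", "w")],
    a2[c("source", "target", "port", "epsilon", "w")]
  )
  aFull <- buildNetwork(defaultConfig(scale = 0.125), seed = 1)@audit
  expect_identical(
    a1[c("source", "target", "port", "w")],
    aFull[c("source", "target", "port", "w")]
  )
})

test_that("zero connection probability leaves only generator wiring", {
  cfg <- defaultConfig(scale = 0.1,
    epsEE = 0, epsEI = 0, epsIE = 0, epsII = 0
  )
  net <- buildNetwork(cfg, seed = 3)
  expect_equal(length(net@connSrc), 0)
  expect_true(all(net@audit$nConnections == 0))
})
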