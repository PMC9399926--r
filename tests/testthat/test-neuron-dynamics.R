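# Exactness and event semantics of the clock-driven neuron update.

test_that("resting state is a fixed point and leak decay follows tau_m", {
  params <- excParamsRef()
  res <- kernelSingleNeuron(
    params, c(5, 2), data.frame(time = numeric(0), port = integer(0),
      amp = numeric(0)),
    nSteps = 1000, dt = 0.1
  )
  expect_true(all(res$v_trace[, 1] == params@vRest))
  # depolarized start decays with e-fold time tauM: after 20 ms the
  # deviation is 10/e mV
  res <- kernelSingleNeuron(
    params, c(5, 2), data.frame(time = numeric(0), port = integer(0),
      amp = numeric(0)),
    nSteps = 400, dt = 0.1, vInit = params@vRest + 10
  )
  dev <- res$v_trace[, 1] - params@vRest
  expect_equal(dev[200], 10 * exp(-1), tolerance = 1e-9)
  expect_equal(dev[400], 10 * exp(-2), tolerance = 1e-9)
})

test_that("subthreshold trajectory is exact against a dense RK4 reference", {
  params <- excParamsRef()
  set.seed(7)
  # an arbitrary mixed spike train over AMPA-like and GABA-like channels
  arrivals <- data.frame(
    time = sort(round(runif(25, 1, 60), 1)),
    port = sample(1:2, 25, replace = TRUE),
    amp = round(runif(25, -40, 60), 2)
  )
  taus <- c(2, 5)
  res <- kernelSingleNeuron(params, taus, arrivals, nSteps = 800, dt = 0.1)
  ref <- refSubthreshold(
    params,
    data.frame(
      time = arrivals$time, amp = arrivals$amp,
      tau = taus[arrivals$port]
    ),
    tEnd = 80, dt = 1e-3, method = "rk4"
  )
  # compare on the coarse grid (kernel reports v at the end of each step)
  idx <- round(seq(0.1, 80, by = 0.1) / 1e-3) + 1
  expect_lt(max(abs(res$v_trace[, 1] - ref$v[idx])), 1e-4)
})

test_that("threshold crossing resets, spikes at end of step, enforces refractoriness", {
  params <- excParamsRef()
  # a strong input spike drives the neuron over threshold
  amp <- pscAmplitude(params, 2) * 25
  res <- kernelSingleNeuron(
    params, 2, data.frame(time = 1, port = 1L, amp = amp),
    nSteps = 300, dt = 0.1
  )
  expect_length(res$time_ms, 1)
  tSpike <- res$time_ms[1]
  # v is clamped at reset throughout the refractory period
  clampIdx <- which(
    seq(0.1, 30, by = 0.1) > tSpike &
      seq(0.1, 30, by = 0.1) <= tSpike + params@tRef
  )
  expect_true(all(res$v_trace[clampIdx, 1] == params@vReset))
})

test_that("no two spikes of one neuron are closer than the refractory period", {
  params <- excParamsRef()
  res <- DecisionNet:::.simulate_trial_cpp(
    0L, params@vRest, params@tauM, params@cM, params@vTh, params@vReset,
    params@tRef,
    5, 5L, integer(0), integer(0), integer(0), numeric(0),
    30000, pscAmplitude(params, 5) * 0.04 * 4, 0L,
    numeric(20000), numeric(20000), 0, 0L,
    matrix(0, 0, 4), 0.1, 20000L, integer(0), numeric(0)
  )
  expect_gt(length(res$time_ms), 10)
  expect_true(all(diff(res$time_ms) >= params@tRef))
})

test_that("a delivered spike arrives exactly one port delay after emission", {
  # two neurons: 0 drives 1 through a port with a 2.5 ms delay; neuron 1's
  # membrane must first move exactly (delay + dt) after the presynaptic
  # spike time (current jumps at +delay, voltage responds one step later)
  params <- excParamsRef()
  dt <- 0.1
  strong <- pscAmplitude(params, 2) * 30
  weak <- pscAmplitude(params, 2) * 0.04
  res <- DecisionNet:::.simulate_trial_cpp(
    c(0L, 0L),
    rep(params@vRest, 2), rep(params@tauM, 2), rep(params@cM, 2),
    rep(params@vTh, 2), rep(params@vReset, 2), rep(params@tRef, 2),
    2, 25L,
    0L, 1L, 0L, weak,
    c(0, 0), c(0, 0), 0L,
    numeric(600), numeric(600), c(0, 0), 0L,
    matrix(c(10, 0, 0, strong), 1, 4), dt, 600L, 1L, numeric(0)
  )
  expect_length(res$time_ms, 1) # only the driven presynaptic neuron fires
  tSpike <- res$time_ms[res$neuron_id == 1]
  vB <- res$v_trace[, 1]
  firstMove <- seq(dt, 60, by = dt)[which(vB != params@vRest)[1]]
  expect_equal(firstMove, tSpike + 2.5 + dt, tolerance = 1e-9)
})

test_that("identical seed and configuration give identical spike records", {
  cfg <- defaultConfig(scale = 0.1)
  prot <- trialProtocol(0.512, tPre = 100, tStim = 300, tPost = 100)
  s1 <- runTrial(cfg, prot, seed = 99)
  s2 <- runTrial(cfg, prot, seed = 99)
  expect_identical(s1@time, s2@time)
  expect_identical(s1@id, s2@id)
  s3 <- runTrial(cfg, prot, seed = 100)
  expect_false(identical(s1@time, s3@time))
  # a pre-built network is reusable and equally deterministic
  net <- buildNetwork(cfg, seed = 5)
  n1 <- runTrial(net, prot, seed = 99)
  n2 <- runTrial(net, prot, seed = 99)
  expect_identical(n1@time, n2@time)
  expect_identical(n1@id, n2@id)
})

test_that("a silent network produces an empty spike record", {
  cfg <- defaultConfig(scale = 0.05,
    noiseExc = c(1e-6, 0), noiseInh = c(1e-6, 0), mu0 = 0
  )
  s <- runTrial(cfg, trialProtocol(0, tPre = 50, tStim = 100, tPost = 50),
    seed = 1)
  expect_length(s@time, 0)
  out <- classifyTrial(s)
  expect_identical(out@winner, "none")
})
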