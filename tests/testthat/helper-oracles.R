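# Independent reference integrators for the subthreshold membrane equation.
# These deliberately avoid the exact-propagator math used by the simulator:
# the synaptic current is evaluated analytically on a dense grid and the
# voltage ODE is integrated numerically (forward Euler or classic RK4).

# analytic synaptic current (pA) on a time grid from a set of input spikes;
# spikes: data.frame(time, amp, tau)
refCurrent <- function(grid, spikes) {
  total <- numeric(length(grid))
  for (k in seq_len(nrow(spikes))) {
    dtk <- grid - spikes$time[k]
    on <- dtk >= 0
    total[on] <- total[on] + spikes$amp[k] * exp(-dtk[on] / spikes$tau[k])
  }
  total
}

# dense-step subthreshold integration; returns v on grid seq(0, tEnd, dt).
# method "euler": v_{k+1} = v_k + h f(t_k, v_k);
# method "rk4": classic Runge-Kutta exploiting the affine structure of
#   f(t, v) = -(v - vRest)/tauM + I(t)/cM, so the whole trajectory reduces
#   to a linear recurrence evaluated with stats::filter.
refSubthreshold <- function(params, spikes, tEnd, dt = 1e-3,
                            method = c("euler", "rk4"), v0 = NULL) {
  method <- match.arg(method)
  tauM <- params@tauM
  cM <- params@cM
  vRest <- params@vRest
  if (is.null(v0)) v0 <- vRest
  grid <- seq(0, tEnd, by = dt)
  nStep <- length(grid) - 1
  if (method == "euler") {
    u <- refCurrent(grid, spikes) / cM # mV/ms drive
    a <- dt / tauM
    drive <- dt * (vRest / tauM + u[seq_len(nStep)])
    v <- stats::filter(drive, 1 - a, method = "recursive",
      init = 0)
    v <- as.numeric(v) + v0 * (1 - a)^seq_len(nStep)
    return(list(time = grid, v = c(v0, v)))
  }
  # rk4: forcing sampled at t, t + dt/2, t + dt
  u1 <- refCurrent(grid[seq_len(nStep)], spikes) / cM
  uh <- refCurrent(grid[seq_len(nStep)] + dt / 2, spikes) / cM
  u4 <- refCurrent(grid[-1], spikes) / cM
  m <- -1 / tauM
  e <- vRest / tauM
  # k1 = m v + e + u1
  # k2 = m v + e + uh + (m dt / 2) k1
  # k3 = m v + e + uh + (m dt / 2) k2
  # k4 = m v + e + u4 + (m dt) k3
  # v+ = v + dt/6 (k1 + 2 k2 + 2 k3 + k4): affine in v -> C v + D
  q <- m * dt
  c1v <- m; c1c <- e
  c2v <- m * (1 + q / 2); c2c <- e + (q / 2) * e
  c3v <- m * (1 + q / 2 + q^2 / 4)
  c4v <- m * (1 + q + q^2 / 2 + q^3 / 4)
  C <- 1 + dt / 6 * (c1v + 2 * c2v + 2 * c3v + c4v)
  # constant and input-dependent forcing, expanded the same way
  d1 <- e + u1
  d2 <- e + uh + (q / 2) * d1
  d3 <- e + uh + (q / 2) * d2
  d4 <- e + u4 + q * d3
  D <- dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
  v <- stats::filter(D, C, method = "recursive", init = 0)
  v <- as.numeric(v) + v0 * C^seq_len(nStep)
  list(time = grid, v = c(v0, v))
}

# dense-step leaky integrate-and-fire with threshold, reset and refractory
# period, forward Euler, driven by input spikes; returns emitted spike
# times. The Euler recurrence between threshold crossings is evaluated
# segment-wise with stats::filter (identical numbers to the scalar loop).
refLIF <- function(params, spikes, tEnd, dt = 1e-3) {
  grid <- seq(0, tEnd, by = dt)
  # exact exponential decay of the summed current, one tau at a time:
  # I_{k+1} = I_k exp(-dt/tau) + charge injected in step k
  current <- numeric(length(grid))
  for (tau in unique(spikes$tau)) {
    inj <- numeric(length(grid))
    sel <- spikes$tau == tau
    bins <- pmin(floor(spikes$time[sel] / dt) + 1L, length(grid))
    for (b in seq_along(bins)) {
      inj[bins[b]] <- inj[bins[b]] + spikes$amp[sel][b]
    }
    current <- current + as.numeric(
      stats::filter(inj, exp(-dt / tau), method = "recursive", init = 0)
    )
  }
  u <- current / params@cM
  a <- dt / params@tauM
  drive <- dt * (params@vRest / params@tauM + u)
  n <- length(grid)
  out <- numeric(0)
  k <- 1L # next step to integrate
  v0 <- params@vRest
  while (k <= n) {
    seg <- k:n
    v <- as.numeric(
      stats::filter(drive[seg], 1 - a, method = "recursive", init = 0)
    ) + v0 * (1 - a)^seq_along(seg)
    hit <- which(v >= params@vTh)[1]
    if (is.na(hit)) break
    out <- c(out, grid[k + hit - 1L])
    v0 <- params@vReset
    k <- k + hit - 1L + as.integer(ceiling(params@tRef / dt)) + 1L
  }
  out
}

# direct kernel invocation for a single neuron with scheduled input spikes
# (arrival times in ms); returns the per-step voltage trace
kernelSingleNeuron <- function(params, portTaus, arrivals, nSteps,
                               dt = 0.1, vInit = numeric(0)) {
  ext <- if (nrow(arrivals)) {
    cbind(
      round(arrivals$time / dt), 0, arrivals$port - 1L, arrivals$amp
    )
  } else {
    matrix(0, 0, 4)
  }
  res <- DecisionNet:::.simulate_trial_cpp(
    0L,
    params@vRest, params@tauM, params@cM, params@vTh, params@vReset,
    params@tRef,
    portTaus, rep(5L, length(portTaus)),
    integer(0), integer(0), integer(0), numeric(0),
    0, 0, 0L,
    numeric(nSteps), numeric(nSteps), 0, min(1L, length(portTaus) - 1L),
    ext, dt, as.integer(nSteps), 0L, vInit
  )
  res
}

excParamsRef <- function() neuronParams(-70, -50, -55, 20, 500, 2)
inhParamsRef <- function() neuronParams(-70, -50, -55, 10, 200, 1)
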