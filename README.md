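# DecisionNet

A spiking attractor network for binary perceptual decision-making, in R.

In the random-dot motion discrimination task, a subject reports which of
two directions a partially coherent dot cloud is moving in; neurons in
parietal cortex (area LIP) ramp up during the stimulus at a rate that
grows with motion coherence, and hold elevated activity through the delay
until the response. DecisionNet implements the standard circuit model of
this computation: two stimulus-selective excitatory populations (A and B)
of leaky integrate-and-fire neurons with AMPA- and NMDA-type exponential
postsynaptic currents, competing through a shared inhibitory population.
The slow NMDA decay constant (100 ms) integrates the noisy evidence; the
feedback inhibition turns the integrated difference into a winner-take-all
choice whose elevated firing persists after the stimulus ends.

The stimulus is a pair of Poisson generators whose rates encode the signed
coherence `c` through the symmetric linear model

    mu_A = mu0 (0.5 - 0.5 c),   mu_B = mu0 (0.5 + 0.5 c),

with `mu0 = 772` Hz, resampled every 25 ms with SD `sigma0 = 48` Hz.
Synaptic weights are dimensionless multiples `w` of a unitary PSP
amplitude `J = 0.04` mV (peak-normalized per target cell class and
receptor channel). The decision readout follows the standard convention:
the winner is the first population whose rate sustains 15 Hz after
stimulus onset, and the reaction time is measured from onset. Performance
versus coherence is summarized by the Weibull neurometric function

    %correct = 1 - 0.5 exp(-(c / alpha)^beta).

The package provides the exact-propagator simulator (C++ core), the
network builder, the stimulus/protocol layer, analysis (rate traces,
decisions, reaction times, decision-space trajectories, Weibull fits) and
the scripted experiments: coherence-sweep batches, the zero-coherence
"coin toss", stimulus-duration and decision-reversal sweeps, and two
mechanism ablations (reduced recurrent potentiation; fast NMDA). See the
methods vignette (`vignettes/decision-network-methods.Rmd`) for the model,
its free parameters and their calibration, and known limitations.

## A worked example

One trial of the 1,000-neuron network at 51.2% coherence toward B:

```r
library(DecisionNet)

cfg <- defaultConfig(scale = 0.5)   # A = B = 400, I = 200
spk <- runTrial(cfg, trialProtocol(coherence = 0.512), seed = 42)
spk
#> SpikeTrains: 55939 spikes from 1000 neurons over 3000 ms; stimulus +51.2% in [500, 1500] ms
#>   mean rates: A 0.48 Hz, B 28.78 Hz, I 34.72 Hz

classifyTrial(spk)
#> TrialOutcome: B wins at 230 ms (correct), persisted
```

Population B ramps up during the stimulus, crosses the 15 Hz decision
threshold 230 ms after stimulus onset, suppresses population A via the
interneurons, and keeps firing at ~25-30 Hz through the 1.5 s delay — the
working-memory trace of the decision. `populationRate()` and
`decisionSpace()` expose the underlying traces.

The coin toss — an ambiguous stimulus with its fluctuations removed, so
only background noise can break the symmetry:

```r
ct <- coinToss(cfg, nTrials = 20, seed = 7)
cat(sprintf("A %.0f%% / B %.0f%% of %d decided\n",
            ct$pctA, ct$pctB, ct$nDecided))
#> A 40% / B 60% of 20 decided
```

A neurometric curve and its Weibull fit from a small sweep of population
A's preferred coherences:

```r
b <- runBatch(cfg, coherences = -c(3.2, 6.4, 12.8, 25.6, 51.2),
              nTrials = 10, seed = 11)
curve <- neurometricCurve(b$summary, population = "A")
fitWeibull(curve$coherence_pct, curve$pctCorrect)
#> NeurometricFit: alpha = 8.15% coherence, beta = 1.56 (RMS residual 0.0351)
```

`alpha` is the coherence at which the network is right about 81.6% of the
time; `beta` sets the steepness of the transition from chance to certainty.

A command-line front end over the same functions is installed at
`inst/scripts/decisionnet.R`:

```sh
Rscript inst/scripts/decisionnet.R simulate --coherence 51.2 --seed 7 --out out/run1
Rscript inst/scripts/decisionnet.R coin-toss --trials 100 --seed 1 --out out/coin
Rscript inst/scripts/decisionnet.R show-config
```

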