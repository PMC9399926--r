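---
title: "The DecisionNet model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DecisionNet model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DecisionNet)
```

# The scientific problem

In the classic random-dot motion discrimination task, a subject watches a
cloud of dots of which a fraction *c* (the *coherence*) moves coherently in
one of two directions, and reports the perceived direction with a saccade.
Neurons in the lateral intraparietal area (LIP) show slow ramping activity
during the stimulus whose rate of rise grows with coherence, and elevated
persistent activity through the post-stimulus delay — the neural signature
of evidence accumulation and of a working-memory trace of the choice.

DecisionNet implements the standard two-population attractor model of this
process: a recurrent excitatory–inhibitory spiking network in which two
excitatory populations (A and B), each selective for one direction, compete
through shared feedback inhibition. Slow recurrent excitation through
NMDA-type synapses (decay constant 100 ms) lets the network integrate its
noisy inputs over hundreds of milliseconds; once one population gains an
advantage, the interneurons translate it into suppression of the rival —
a winner-take-all transition into one of two attractor states that outlasts
the stimulus.

# Neuron and synapse model

Both cell classes are current-based leaky integrate-and-fire neurons with
multi-port exponential postsynaptic currents:

$$\tau_m \frac{dV}{dt} = -(V - E_L) + \frac{1}{g_L}\sum_p I_p(t),
  \qquad \tau_p \frac{dI_p}{dt} = -I_p,$$

with $g_L = C_m/\tau_m$. A presynaptic spike arriving at port $p$ steps
$I_p$ by the synapse's amplitude after the port's conduction delay. When
$V$ reaches $V_{th}$ the neuron emits a spike, is reset to $V_{reset}$ and
is clamped there for the refractory period $t_{ref}$, during which synaptic
currents keep evolving. Spike-frequency adaptation, external DC currents
and conductance-based (voltage-dependent) synapses are deliberately absent:
the NMDA channel is distinguished solely by its slow decay constant, which
is the one property that carries the slow-reverberation mechanism. The
receptor channels are:

| port  | $\tau_{syn}$ (ms) | delay (ms) | sign |
|-------|------:|-----:|-----:|
| NOISE | 5     | 0.5  | +    |
| AMPA  | 2     | 0.5  | +    |
| NMDA  | 100   | 2.5  | +    |
| GABA  | 5     | 0.5  | −    |

The 2.5 ms NMDA delay absorbs the ~2 ms rise time that the
instantaneous-jump current model cannot otherwise express.

Membrane constants (excitatory / inhibitory): $E_L = -70$ mV,
$V_{th} = -50$ mV, $V_{reset} = -55$ mV, $\tau_m = 20/10$ ms,
$C_m = 500/200$ pF, $t_{ref} = 2/1$ ms.

## Weight normalization

Synaptic strengths are specified as dimensionless multipliers $w$ of a
common unitary PSP amplitude $J = 0.04$ mV. For each (target cell class,
port) pair, `pscAmplitude()` returns the current amplitude whose single-spike
PSP peaks at exactly 1 mV:

$$\mathrm{PSP}(t) = A\,\frac{\tau_m \tau_s}{C_m(\tau_m - \tau_s)}
  \left(e^{-t/\tau_m} - e^{-t/\tau_s}\right),
  \qquad t^\* = \frac{\tau_m \tau_s}{\tau_m - \tau_s}
  \ln\frac{\tau_m}{\tau_s},$$

and the synapse's amplitude is $A \cdot J \cdot w$ (negative for GABA).
In the singular limit $\tau_s = \tau_m = \tau$ the PSP is the alpha
function $A\,t\,e^{-t/\tau}/C_m$ with peak $A\tau/(C_m e)$; the limit
formula is used when the two constants are within $10^{-9}$ ms. None of the
default port/class combinations is singular (the closest is the inhibitory
membrane, 10 ms, against the NOISE/GABA channels, 5 ms).

## Exact propagation

The subthreshold system is linear, so each 0.1 ms step applies the exact
propagator

$$V \leftarrow E_L + (V - E_L)e^{-\Delta t/\tau_m}
  + \sum_p G_p I_p, \qquad I_p \leftarrow I_p e^{-\Delta t/\tau_p},$$

$$G_p = \frac{\tau_m \tau_p}{C_m(\tau_m - \tau_p)}
  \left(e^{-\Delta t/\tau_m} - e^{-\Delta t/\tau_p}\right),$$

which removes all step-size artifacts from the PSP peaks that the weight
normalization relies on; the test suite verifies the trajectory against a
dense Runge–Kutta reference to $10^{-4}$ mV. Threshold is checked once per
step and a crossing emits the spike at the end of the step — the standard
grid-constrained convention, which is deterministic and caps the timing
error at $\Delta t$. Delayed delivery uses one ring buffer per port; a
spike emitted at time $s$ steps the target current exactly at $s + $ the
port's delay. With all delays at least 0.5 ms and $\Delta t = 0.1$ ms the
update order inside a step can never create a same-step causal loop.

# Network architecture

2,000 neurons by default: A = B = 800 excitatory, I = 400 inhibitory
(`defaultConfig(scale = )` preserves the 2:2:1 ratio). Projections, all
wired with the pairwise-Bernoulli rule (each ordered pair connected
independently with probability $\epsilon$, no autapses, fixed weights):

* within-population recurrence A→A, B→B: AMPA at $w_+ = 1.7$ and NMDA at
  $w_{NMDA} = 4.25$ (potentiated);
* cross-population A→B, B→A: AMPA and NMDA, both depressed by
  $w_- = 0.8$;
* excitatory → inhibitory: AMPA and NMDA at $w_+ = 1.7$;
* inhibitory → excitatory and inhibitory → inhibitory: GABA.

Every neuron receives an independent background Poisson generator on the
NOISE channel whose rate is drawn once per trial from a Gaussian
(7719 ± 38 Hz to excitatory, 5789 ± 28 Hz to inhibitory cells); the two
stimulus generators attach to every neuron of their excitatory population
on the AMPA channel.

## Free parameters and calibration

The standard parameterization fixes the membrane constants, time
constants, delays, $J$, $w_+$, $w_-$, $w_{NMDA}$, the stimulus statistics
and the background rates — but not the connection probabilities, the
inhibitory weights, or the weights of the generator projections. These
remaining dimensionless knobs were calibrated **once**, before any
statistical experiments were run, to put the network into the operating
regime the model requires, and are frozen as package defaults:

* $\epsilon_{EE} = 0.03$, $\epsilon_{EI} = 0.025$,
  $\epsilon_{IE} = \epsilon_{II} = 0.1$ at the 1,000-neuron reference
  scale, rescaled inversely with population size so expected in-degrees
  (and hence the mean recurrent drive per neuron) are size-invariant;
* $w_{IE} = 8$, $w_{II} = 1$ for the GABA projections;
* background-generator weights $w_{noise}^{exc} = 1.90$,
  $w_{noise}^{inh} = 3.85$; stimulus-generator weight $w_{stim} = 1$.

The calibration targets were qualitative and taken from the model's own
description of its dynamics: a stable spontaneous state with excitatory
cells at ~1 Hz and interneurons at ~5 Hz; stimulus-driven winner-take-all
reaching a 25–35 Hz attractor with the loser suppressed below a few Hz;
persistent winner activity throughout the post-stimulus delay; no
saturation (rates pinned at the refractory ceiling) or global oscillation;
and a zero-coherence regime in which essentially every trial reaches a
decision within the 3 s trial — driven by the background noise, not by the
stimulus fluctuations — while no population ignites before stimulus onset.
Two structural facts drive the calibrated values. First, with every unitary
PSP fixed at 0.04 mV, the tabulated background rates alone leave both cell
classes far below threshold, so the generator projections need
(class-specific) potentiation exactly like the recurrent ones — the
interneurons, with their smaller membrane resistance and lower noise rate,
need proportionally more. Second, the NMDA recurrence at
$w_{NMDA} = 4.25$ with a 100 ms decay is so strong per connection that a
uniform connection probability either extinguishes the network or drives
it to the refractory ceiling; a sparser E→E graph with a denser, stronger
inhibitory loop yields the intermediate attractor.

# Stimulus model

The two generators share a total rate $\mu_0 = 772$ Hz through the
symmetric linear code
$$\mu_A = \mu_0(0.5 - 0.5c), \qquad \mu_B = \mu_0(0.5 + 0.5c),$$
so $\mu_A + \mu_B = \mu_0$ for every signed coherence $c \in [-1, 1]$
(positive favors B). During the stimulus epoch the actual rate of each
generator is redrawn every 25 ms from $N(\mu_X, \sigma_0^2)$ with
$\sigma_0 = 48$ Hz, clipped at zero (at the default means clipping is
essentially never active); $\sigma_0 = 0$ switches the fluctuations off,
the mode used in the coin-toss experiment. Background rates are drawn once
per neuron per trial; only the stimulus is block-resampled.

The default trial is 3 s: 500 ms baseline, 1,000 ms stimulus, 1,500 ms
delay, all configurable per protocol, with optional mid-stimulus coherence
reversal at block resolution. Trials are independent and start from rest;
no inter-trial state is carried.

# Readouts

Population rates are sliding-window estimates (50 ms causal window, 5 ms
step; optional running-median filter). The decision rule follows the
standard threshold convention: the winner is the first population whose
rate reaches 15 Hz after stimulus onset and stays there for two
consecutive grid points (the sustained requirement rejects single-window
noise blips); the reaction time is measured from stimulus onset. A
simultaneous crossing is broken by the larger rate at the crossing, then
by label A, and flagged. Persistence is reported two ways: a strict flag
(winner above loser at every grid point of the delay) and a graded ratio
(mean winner rate over the last 500 ms of the delay divided by its
stimulus-epoch peak); "no persistent activity" in the ablation analyses
means a ratio below 1/3.

The neurometric function is percent correct versus coherence (percent
units), fitted with the Weibull form
$$\%\,correct = 1 - 0.5\,e^{-(c/\alpha)^\beta}$$
by Levenberg–Marquardt least squares. Percent correct is computed among
decided trials; undecided trials are reported separately rather than
counted as errors, since the threshold rule, not the competition, failed
to resolve them. Degenerate inputs (all at chance, all saturated, fewer
than three levels) yield a flagged non-converged fit rather than an error.

# Experiments

`runBatch()` runs one independent trial per (coherence, replicate), each
with its own connectivity, background and stimulus realization, all
derived from a single master seed through fixed substreams — a batch is a
pure function of (configuration, coherences, n, seed, protocol).
`coinToss()` (coherence 0, optionally $\sigma_0 = 0$) measures the choice
split when only background noise can break the symmetry. `durationSweep()`
shortens the stimulus; `reversalSweep()` flips the coherence mid-stimulus,
either at varying times (±6.4%) or at varying reversed intensities after
1 s of 12.8%. `ablationRun()` repeats a batch with one mechanism removed,
on the same per-trial seeds as its control:

* **reduced recurrent potentiation** ($w_+: 1.7 \to 1.4$). The
  potentiation is interpreted as a property of the within-population
  recurrent *synapses*, so it scales both receptor components: the AMPA
  weight goes to 1.4 and the NMDA multiplier is reduced proportionally
  ($4.25 \to 3.5$), while the excitatory–inhibitory pathway stays at
  control strength. Implemented this way the ablation reproduces the
  expected phenotype — winner-take-all still forms under a strong stimulus
  but the winner's activity collapses once the stimulus ends, and no
  categorical decision forms at low coherence. Two alternatives were tried
  and rejected against that phenotype: keeping the NMDA multiplier fixed
  at 4.25 (the within-population AMPA component carries only ~7% of the
  recurrent charge, so that variant acts almost purely through weakened
  inhibition recruitment and *strengthens* the attractor), and scaling the
  E↔I projections together with the recurrence (the loss of excitation and
  the loss of inhibition recruitment partially cancel, leaving the
  attractor largely intact).
* **fast NMDA** ($\tau_{NMDA} = \tau_{AMPA} = 2$ ms, amplitude
  re-normalized to the same PSP peak). Removing the slow tail removes the
  temporal integration: the network never ramps to the decision threshold
  and never suppresses the losing population.

# What the generator emulates — and what it does not

All inputs are internally generated Poisson processes; there is no
external data. The stimulus model emulates the coherence-dependent mean
rates (and their slow fluctuations) of direction-selective sensory
neurons, not the visual display itself: dot kinematics, spatial receptive
fields, and any sensory preprocessing are outside the model, as are eye
movements and everything downstream of the two excitatory populations.
Passing tests therefore validate the attractor mechanism under idealized
Poisson drive with the stated statistics; they do not certify behavior
under structured, correlated, or non-stationary sensory input.

# Numerical and design notes

* $\Delta t = 0.1$ ms (configurable). Delays are validated to be at least
  one step. The step is also the spike-timing resolution.
* Negative Gaussian draws for rates are clipped at zero; at the default
  means the event has negligible probability.
* Spike times are serialized at fixed 1 µs precision — finer than the
  step, so round trips are lossless and files diffable.
* The RNG contract: one master seed expands (via a seeded draw) into
  `connectivity`, `background`, `stimulus` and `simulation` substreams,
  consumed in that documented order; the in-kernel Poisson sampling uses
  R's own generator, so results are identical across platforms that share
  R's RNG.
* Per-trial wiring: batches redraw connectivity each trial, making trials
  exchangeable and the connectivity a noise source, matching how the
  choice-percentage experiments are defined.
* Sign symmetry: the wiring and parameters are exchangeable under
  A↔B together with $c \to -c$; with $\sigma_0 = 0$ the generator mean
  schedules mirror exactly. With $\sigma_0 > 0$ the block noise of the two
  generators is drawn independently (A first, then B), so mirrored runs
  agree in distribution rather than realization-by-realization.

## Problem sizes in the tests and the acceptance script

The statistical experiments are run at the 1,000-neuron scale (the model's
own downscaled variant) with trial counts chosen to keep the suites at
desk scale while leaving the binomial error bars informative: 40–60
trials per condition for winner-take-all, reaction-time and neurometric
checks (five coherence levels), a few hundred zero-coherence trials for
the choice split, 10–20 per condition for ablations and reversals. The full
full-size battery (1,000 trials per condition at 2,000 neurons) is a
straightforward, if long, scale-up of the same calls.

# Known limitations

* The calibrated operating point makes the attractor robust: once a
  population is committed (above roughly 10 Hz with the rival suppressed),
  a late counter-stimulus of even 70–80% coherence rarely overturns the
  decision within a second, because the stimulus current is a ~2%
  perturbation of the background drive while the recurrent NMDA advantage
  of the leader is several times larger. Early reversals (before
  commitment) behave as expected. A regime in which strong late reversals
  reliably flip formed decisions while low-coherence performance stays
  noisy was not found within the standard parameter set; the two demands
  pull the stimulus weight in opposite directions.
* Zero-coherence decisions can form late (occasionally after stimulus
  offset); the few trials that remain undecided within a 3 s trial are
  excluded from choice percentages, which are reported among decided
  trials.
* Because ignition is noise-dominated near the calibrated operating
  point, the network often completes a decision during the delay even
  when the stimulus is cut short: a 500 ms stimulus barely reduces the
  decided fraction relative to 1,000 ms (persistence weakens first), and
  only the no-stimulus limit shows the full reduction.
* The NMDA channel is linear (no voltage dependence, no saturation);
  its phenotype is carried entirely by the 100 ms decay.
* Exchangeability of A and B is exact in the model, so systematic choice
  biases in the data it emulates (side biases of real subjects) are out of
  scope.
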