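---
title: "The barrel-cortex network model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The barrel-cortex network model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`barrelsim` simulates leaky integrate-and-fire (LIF) network models of the
rodent whisker barrel system on a fixed 1-ms clock. This vignette documents
the model, the numerical scheme, the stimulus generator, the three
experiment pipelines, and the design choices that were genuinely open —
together with what the simulations do and do not establish.

## The neuron and synapse model

Each cortical cell is a current-based LIF neuron,

$$\tau_m \frac{dV}{dt} = E_L - V + R_m I,$$

with threshold $V_\Theta$, reset to $V_\mathrm{reset}$, and an absolute
refractory period $t_\mathrm{ref}$. The synaptic current $I$ is the sum of
two accumulators with first-order kinetics,
$\tau_s \, dI/dt = -I$, one per synaptic time constant: an excitatory
accumulator ($\tau_{se} = 5$ ms, $I_e \ge 0$) and an inhibitory one
($\tau_{si} = 15$ ms, $I_i \le 0$). Every arriving spike adds its synaptic
weight $w$ (nA) to the matching accumulator, so a single postsynaptic
current carries charge $w\,\tau_s$ (pC).

Parameters come from paired intracellular recordings in the two modelled
layers:

| parameter | unit | L2/3E | L4E |
|---|---|---|---|
| $E_L$, $V_\mathrm{reset}$ | mV | −72 | −66 |
| $V_\Theta$ | mV | −40 | −40 |
| $\tau_m$ | ms | 30 | 35 |
| $R_m$ | MΩ | 190 | 300 |
| $\tau_{se}$, $\tau_{si}$ | ms | 5, 15 | 5, 15 |
| $t_\mathrm{ref}$ | ms | 10 | 10 |

Inhibitory cells use their layer's excitatory parameters: no interneuron
measurements are available in the source tables, and introducing distinct
physiology would be an invention. Units are consistent throughout
(MΩ · nA = mV); all times are milliseconds.

## Integration: exact propagation on the 1-ms grid

Between spike deliveries, the $(V, I_e, I_i)$ system is linear, and the
package advances it with its exact propagator over each step
(`advance_neuron()`): the currents decay by $e^{-\Delta t/\tau_s}$ and the
membrane receives each current's exact convolution term

$$c_s = R_m \frac{\tau_s}{\tau_s - \tau_m}
  \left(e^{-\Delta t/\tau_s} - e^{-\Delta t/\tau_m}\right).$$

This "exact integration" scheme is the one standard reference simulators
use for current-based LIF models. We chose it over the simpler operator
splitting (membrane advanced with the current held constant, then current
decay) because splitting systematically overestimates every PSC's charge by
a factor $(\Delta t/\tau_s)/(1 - e^{-\Delta t/\tau_s})$ — about 10% at
$\tau_{se} = 5$ ms and $\Delta t = 1$ ms — which shifts trajectories by
several tenths of a millivolt per PSC. With exact propagation, the 1-ms
trajectory coincides with a fine-step integration of the continuous
equations up to the reference integrator's own error; the test suite holds
this to 0.1% of the threshold distance $V_\Theta - E_L$ over 100-ms
trajectories. `step_membrane()` separately exposes the constant-current
closed form, which is exact for current-clamp drive.

Per step $t$ the engine applies a fixed contract:

1. deliver source spikes stamped $t$ and network spikes stamped $t-1$ into
   the target accumulators (all conduction delays are one step, 1 ms — the
   minimal causal choice for a 1-ms clocked system);
2. advance every cortical neuron with the exact propagator;
3. test threshold inclusively ($V \ge V_\Theta$ fires), reset, start the
   refractory period, and record the spike with timestamp $t$.

Refractory bookkeeping decrements the timer before the clamp test, so a
neuron that spiked at step $t$ may spike again at step $t + t_\mathrm{ref}$
and the sustained maximum rate is exactly $1000/t_\mathrm{ref} = 100$ Hz.
(The alternative — testing before decrementing — silently lengthens every
minimum interspike interval to $t_\mathrm{ref} + \Delta t$ and caps the
saturated rate at ~91 Hz, which contradicts the refractory-limited
saturation the sweep experiment measures.) During refractoriness only $V$
is clamped; synaptic currents continue to accumulate and decay.

## Network construction

One barrel: excitatory L4E (3471 cells) and inhibitory L4I (613), all
intracortical projections sampled independently per ordered pair at
$p = 0.1$ (self-pairs included, so a recurrent two-population group
realizes $p(N_e + N_i)^2$ synapses in expectation), driven by a 285-source
thalamic barreloid connected to both cortical populations at $p = 0.25$.
The excitatory weight is fixed at $w_e = 0.1$ nA and the inhibitory weight
follows the balance condition extended to unequal synaptic time constants,

$$|w_i|\,\tau_{si} = b\, w_e\, \tau_{se}\, \frac{N_e}{N_i},$$

which balances PSC *charge* rather than amplitude; $b$ is the balance
coefficient ($b = 1$ is the balance point, $b < 1$ excitation-dominated,
$b > 1$ inhibition-dominated). At the L4 census this gives
$|w_i| = 0.1887$ nA for $b = 1$. The inhibitory-to-excitatory projection is
additionally scaled by `i2e_scale` (1.5 in the stimulated-regime
experiments; 1 in the sweep), applied in both layers of the column model —
the reading that keeps the construction uniform where the source protocol
states the scaling for each layer separately.

A full column adds L2/3E (4507) and L2/3I (795) with the same recurrent
construction (balance computed from the supragranular census:
$|w_i| = 0.1890$ nA) and interlayer projections L4E→L2/3E and L4E→L2/3I at
$p = 0.1$, 0.2 nA. The chain instantiates five columns and connects
neighbouring L2/3E populations bidirectionally at $p = 0.1$, 0.1 nA, with
free ends. Bidirectional laterals are required for the synapse census to
round to the published $5 \times 10^7$ total (49,302,115 expected synapses;
unidirectional laterals would give ~41M). Full-scale totals: 9671 neurons
per column, 48,355 in the chain.

Connectivity is sampled by geometric gap-skipping over the ordered-pair
index — distributionally identical to an independent Bernoulli draw per
pair — under R's seeded RNG, so a model rebuilds bit-identically from its
seed. `scale` shrinks every population proportionally for scaled-down
runs; probabilities are untouched and balance weights are recomputed from
the scaled counts.

### Thalamocortical weight calibration

The thalamocortical weight is defined as the minimum weight that elicits
firing in the barrel *without* intracortical projections under constant
6-Hz Poisson thalamic drive. "Elicits firing" is quantified as a mean L4E
rate of at least 0.1 Hz over a 10-s window — a small positive threshold
over a long window, robust to Poisson fluctuations. The search
(`calibrate_tc_weight()`) brackets by factor-2 steps and bisects to 1%,
holding connectivity and the stimulus realization fixed so the criterion is
monotone in the weight. A mean-field bound caps the result: requiring
$R_m \bar I \ge V_\Theta - E_L$ at the mean drive of
$6\,\mathrm{Hz} \times 285 \times 0.25$ inputs gives $w \approx 0.041$ nA,
and fluctuation-driven firing starts below that; the calibrated value at
full scale is ≈ 0.024 nA.

## Thalamic drive

Thalamic sources are independent inhomogeneous Poisson processes emitted by
Bernoulli thinning on the 1-ms grid: in each bin a source fires with
probability $r(t)\,\Delta t$. The bias relative to an exact point process
is of order $r\,\Delta t \le 3\%$ at the 30-Hz stimulus peak, and the
thinned train is what a 1-ms clocked system delivers anyway. Baseline rate
is 6 Hz (the in-vivo spontaneous thalamic rate under the experimental
conditions the model targets).

A whisker-deflection **onset** is a rate triangle rising 6 → 30 Hz in 5 ms
and decaying back in 30 ms; an **offset** is the mirrored triangle (30-ms
rise, 5-ms fall). Where triangles could overlap the instantaneous rate is
the maximum of baseline and the active triangles; at the protocol timings
they never overlap. A single-deflection battery is 500 ms of rest, one
onset, and one offset 150 ms later; the chain battery is 500 ms of rest
followed by five onset/offset pairs at 10 Hz. The onset–offset lag within
a chain repetition is not specified by the protocol; we centre it (50 ms),
which keeps each offset clear of the following onset's triangle.

## Experiments

All three pipelines derive every seed from one master seed (connectivity,
calibration, per-trial stimuli), so any trial can be reproduced in
isolation. Each battery is simulated as an independent run with a fresh
stimulus seed — equivalent to concatenation given the rest period, and
convenient for scaling.

**Initial conditions.** The engine's default start is deterministic
($V = E_L$, currents zero). The experiment pipelines instead draw each
trial's initial potentials uniformly on $[E_L, V_\Theta)$ from the trial
seed. The reason is measured, not aesthetic: a network started cold at
$E_L$ charges silently for roughly $5\tau_m \approx 175$ ms and then
ignites with a near-full population spike. In the sweep (which has no rest
period) the dead time drags a saturated regime's one-second mean from the
true sustained 100 Hz down to ~85 Hz, and in the battery protocols the
ignition burst lands *inside* the rest period and contaminates the
spontaneous-rate baseline. Uniform initial potentials are the standard
convention for steady-state rate measurements in balanced-network models.

**Balance sweep** (`balance_sweep()`): for each $b$ on a log-spaced grid
(default 25 points on $[0.1, 10]$; the acceptance run uses
$\{0.1, 0.5, 1, 2, 10\}$), build the barrel with `i2e_scale = 1` and the
same connectivity seed (only weights change across $b$), run trials of 1 s
at 6-Hz drive, and record the mean and SD of the per-trial mean L4E rate.
The curve saturates near the refractory-limited 100 Hz for small $b$,
collapses through a sharp transition near $b = 1$, and approaches silence
at $b = 10$.

**Response transformation** (`response_transformation()`): 10 independently
sampled barrels at $b = 1$, `i2e_scale = 1.5`, 25 single-deflection
batteries each. Summary statistics per instance: spontaneous L4E rate over
the rest window [100, 500) ms, and the peak of the battery-aligned PSTH in
the 50 ms after the onset and after the offset. The two transformations
under test: spontaneous cortical excitatory rates sit well below the 6-Hz
thalamic rate (measured ≈ 2 Hz), and onset responses beat offset responses
(peak ordering holds in 8/10 instances at the full protocol scale under
the packaged seeds).

**Chain propagation** (`chain_experiment()`): the five-column chain at the
same balance; column 0's thalamus receives five chain batteries, all other
thalami 6-Hz baseline. Outputs: battery-aligned PSTHs per population and
column, per-cell spike counts summed over the 25-ms windows after each of
the 25 deflection onsets, and an evoked-response table. "Evoked" means
any post-onset PSTH bin exceeding the pre-battery baseline mean by 3
baseline SDs — the source protocol asserts presence/absence without a
criterion, so one had to be fixed; 3 SDs on the default 5-ms bins is
conventional but, under the bursty dynamics described below, prone to
false positives when many bins are tested.

## Spike-train analysis and file format

`mean_rate()` divides in-window events by population size and window
length; windows are half-open `[t0, t1)` with 0-based millisecond
timestamps throughout. `psth()` re-references events to each alignment
time and normalizes to Hz per neuron per presentation
(`count / (n_neurons × n_presentations × bin_width)`), 5-ms bins by
default; the total integral times neurons times presentations recovers the
event count exactly. `window_counts()` sums per-neuron events over the
union of half-open post-onset windows (25 ms by default). Spike files are
self-describing plain text — `#` headers carrying duration, timestep and
the population map, then one `time<TAB>id` event per line — because no
universal interchange format for spike trains exists; the round trip is
lossless. Count-map heat maps are normalized per population row only at
plotting time, never in stored data.

## Problem sizes and runtime

The packaged tests run the dynamics oracle and census checks in seconds;
the sweep at five $b$ values × 3 trials × 1 s; the transformation at its
full protocol scale (10 instances × 25 batteries, ~700-ms runs); and the
chain at full scale (48,355 neurons, ~49.3M realized synapses, five 1-s
batteries). The compiled engine simulates the full chain at roughly
realtime on one core; building the chain's connectivity takes on the order
of a minute.

## Known limitations

* **Population-spike-dominated dynamics.** With the published weights
  ($w_e = 0.1$ nA across $R_m = 300$ MΩ, i.e. ~3-mV PSPs) and 25% shared
  thalamic input, the spontaneous balanced state is not asynchronous
  irregular: activity is carried by intermittent near-population-wide
  bursts. Mean rates, the sweep sigmoid, and the onset/offset asymmetry
  survive this, but any statistic assuming Poisson-like spontaneous
  activity (such as the 3-SD evoked criterion) inherits heavy-tailed bin
  statistics.
* **Supragranular saturation in the chain.** The interlayer feed
  (0.2 nA × ~347 synapses per L2/3 cell) is more than an order of
  magnitude suprathreshold at the granular layer's spontaneous rate. In a
  lossless simulation the supragranular layers therefore lock into a
  synchronized ~100-Hz state: with every delay equal to 1 ms, each fresh
  excitatory volley arrives one step ahead of the inhibition it recruits.
  The original hardware experiments ran in a regime where per-processor
  spike loss at rates near 100 Hz is documented; such loss (deliberately
  not modelled here — the reference behaviour is lossless) would break
  exactly this lock. Consequently the chain pipeline reproduces the
  architecture, census and stimulus protocol faithfully, and confinement
  of thalamic drive to column 0, but not a low-rate propagating
  supragranular response; the corresponding acceptance checks are expected
  to fail and are left failing rather than redefined.
* The thinned Poisson sources are rate-modulated point processes only: no
  thalamic bursting, adaptation or refractoriness.
* All synapses within a projection share one weight, as in the source
  model; there are no weight distributions, no plasticity, and no
  transmission failures.
* Synthetic drive only: the generator emulates the statistical structure
  of the in-vivo-like thalamic input (rates, triangles, battery timing),
  not mechanical whisker dynamics — passing tests demonstrate fidelity to
  the specified model, not to biological barrel cortex.
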