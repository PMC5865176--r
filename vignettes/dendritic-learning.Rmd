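---
title: "Synaptic versus dendritic STDP in a LIF perceptron: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic versus dendritic STDP in a LIF perceptron: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendriteLIF)
```

## The model and its assumptions

`dendriteLIF` simulates a feedforward perceptron: `N` excitatory input
units project onto one leaky integrate-and-fire output unit. Input `i`
reaches the output after a fixed delay `d_i` (ms) through exactly one
dendrite, and its arrival kicks the membrane voltage up by the *effective
weight* `W_i * W_D(i)` — the product of the per-link synaptic weight and
the per-node weight of the dendrite it rides on. Between arrivals the
voltage decays exponentially toward rest with `tau = 20` ms; crossing the
threshold emits an evoked spike, resets the voltage to rest and opens a
2 ms absolute refractory window during which the voltage stays clamped at
rest. Internally everything runs in scaled units (rest 0, threshold 1);
`to_scaled_units()` maps physical parameters (−70 mV rest, −54 mV
threshold) onto that scale, and spike times are identical either way.

Assumptions worth keeping in mind: inputs are excitatory only, delays are
constant, the stimulation is strictly periodic (all inputs driven
simultaneously at 10 Hz), and the neuron is a point neuron — dendrites
enter only as shared multiplicative weights, not as cables.

Because the input is a train of Dirac impulses, the voltage trajectory is
piecewise closed-form. The engine (`simulate_network()`, with an Rcpp
core) is therefore event-driven and exact: it decays analytically from
event to event and never integrates numerically. A deliberately naive
dense fixed-step integrator exists in the test suite as an independent
cross-check of the event ordering, refractory, threshold, pairing and
update logic.

## The plasticity rule

Both learning modes share one pair-based STDP window. Every pairing of an
evoked spike with a *sub-threshold stimulation* — an arrival that does not
evoke a spike — at time-lag `Delta = t_sub - t_spike` multiplies the
sub-threshold event's own adaptive weight by `1 + dW` with

```
dW = 0.05 * exp(-|Delta|/15) * sign(Delta)
```

cut off beyond 50 ms (inclusive at the boundary), zero at `Delta = 0`, and
a floor of 0.001 on the adaptive weights. A sub-threshold arrival *after*
the spike strengthens; one *before* weakens. The sign orientation is
forced by the worked two-dendrite example: the right dendrite receives
sub-threshold arrivals 5 ms before and 3 ms after the left dendrite's
spike and must strengthen on net, which
`(1 + dW(+3)) * (1 + dW(-5)) - 1 = +0.0036` per cycle delivers.

Mode selects the adaptive set and the exclusion rule: synaptic mode adapts
`W_i` and excludes pairs sharing an input; dendritic mode adapts `W_Di`
and excludes pairs sharing a dendrite. The frozen set never moves — an
invariant the tests assert on every trace.

Three contract details were genuinely open, and the package fixes them as
follows:

* **Pair multiplicity.** Each new event pairs with *every* eligible
  counterpart inside the 50 ms window, not only the nearest
  (`nearest_only = FALSE` by default; the toggle exists for sensitivity
  analysis). The updates are applied at the time of the later event of
  each pair, in chronological order, which keeps trajectories causal and
  reproducible.
* **Refractory arrivals.** Arrivals inside the refractory window are
  recorded (flagged `during_refractory`) but by default do **not**
  participate in pairing. This is a deliberate deviation from reading
  "stimulation that does not evoke a spike" literally: a refractory
  arrival is silenced by the voltage clamp *no matter how strong its
  weight*, so letting it pair destroys the self-limitation of the
  dynamics — a dendrite whose arrivals all spike or fall in refractory
  windows would strengthen without bound (we observed dendritic weights
  exceeding 1e30 in random ensembles before fixing the default). With
  refractory arrivals excluded, a weight that grows until its arrivals
  spike stops generating sub-threshold events and the learning
  self-limits, which is the behaviour the model is meant to exhibit. The
  literal reading remains available as `pair_refractory = TRUE`.
* **Simultaneous arrivals** are processed in ascending input index, and a
  spike is attributed to the arrival whose jump completes the crossing.
  The published architectures have distinct delays, so this only matters
  for random ensembles.

## Preset architectures

The presets encode the two worked examples. `fig2*`: three inputs, delays
12 | 7, 15 ms, two dendrites (left carries the 12 ms input). `fig3*`:
seven inputs on three dendrites — red {5, 10, 50}, green {20, 25}, orange
{40, 46} ms. The `*_synaptic` / `*_dendritic` suffix selects the learning
mode on the same topology.

The original figures specify initial weights only by colour code, so the
presets encode the *narrated qualitative state* rather than published
numbers; they are interpretations, and documented as such. Two constraints
pin them down:

* Only the intended input may start at threshold, **including
  accumulation**: voltage residuals from earlier sub-threshold arrivals in
  the same cycle must not push a later arrival over threshold. This rules
  out seemingly natural choices — e.g. seven equal weights of 0.7 put the
  second arrival of the three-dendrite preset above threshold through
  summation (0.7 + 0.7·e^{-5/20} ≈ 1.25), and the first spike would come
  at 10 ms instead of 40 ms.
* In the three-dendrite preset, each dendrite fires through a single
  dominant input (5 ms on red, 20 ms on green, 40 ms on orange) while its
  weaker inputs stay sub-threshold. This keeps cross-dendrite pairing
  alive in every phase and lets the narrated loop close: spike at 40 →
  red strengthens via its 50 ms input arriving 10 ms late → spikes at 5
  (and transiently 40, 50) → orange collapses via its 46 ms input just
  before the 50 ms spike → green grows via the 5 ms spike → green fires,
  red weakens via its 10 ms input → orange recovers → green terminates via
  its 25 ms input just before the orange spike → back to the start. With
  symmetric within-dendrite weights the loop is cut short: once *both*
  inputs of a dendrite fire, that dendrite has no sub-threshold events
  left, freezes, and the run is absorbed into a static all-firing state.

With these choices the dendritic presets reproduce the narrated behaviour:
the `"triplet"` two-dendrite variant converges to all effective weights at
or above threshold firing spike triplets, the `"complex"` variant
oscillates with an 11-cycle pattern period, both three-dendrite variants
oscillate with periods of a few thousand cycles, and every synaptic-mode
preset ends at vanishing-or-threshold extremes regardless of initial
weights.

## Classifying weight trajectories

`classify_trajectory()` discards a burn-in (default the first half of the
cycles), then labels the adaptive-weight series:

* **converged** — every adaptive weight moves by less than `tol_converged
  = 1e-4` (relative) over the trailing 100-cycle window *and* the firing
  signature is stable there; *extreme* if each adaptive target has either
  vanished (≤ 0.01) or carries an effective weight at/above threshold,
  else *intermediate*;
* **oscillatory** — the joint sequence of adaptive weights and per-cycle
  firing signatures repeats with some period `p ≥ 2`, verified over three
  full periods at `tol_cycle = 1e-3` relative on weights and 0.01 ms on
  spike offsets, **and** the firing signature changes within the period;
* **undetermined** otherwise.

Two design points deserve explanation. First, the non-constant-signature
requirement is not cosmetic: under a fixed firing pattern every adaptive
weight is multiplied by the same per-cycle factor, so its trajectory is
constant or monotone — a genuine weight oscillation *must* cycle through
different firing patterns. The requirement also prevents a slow monotone
drift from matching trivially at period 2. Second, the weight tolerance is
1e-3 rather than machine-level because limit cycles are approached
geometrically: after 2000 cycles the two-dendrite `"complex"` preset still
carries a ~1e-4 relative residual at its true period. A tolerance of 1e-6
would misclassify genuinely periodic trajectories as undetermined; 1e-3
sits two orders of magnitude above the residual and three below the weight
swings of real oscillations. Fast and slow oscillations are reported
through `period_cycles` rather than as separate labels.

`count_distinct_signatures()` deduplicates asymptotic firing patterns —
converged traces by their stationary signature, oscillatory traces by
their periodic signature sequence up to cyclic rotation — supporting
experiments on how many firing patterns one architecture can express.

## The random ensemble

`sample_config()` draws the initial conditions of the oscillation survey:
delays uniform on [1, 50] ms (continuous by default; an integer-ms toggle
exists for comparison), at least 3 ms between delays on the same dendrite,
the global minimum and maximum delay both on the first dendrite, synaptic
weights uniform on [0.1, 1.8] with at least one effective weight at or
above threshold so firing can start, and all dendritic weights at 1.
Constraints are enforced by rejection sampling with an explicit cap of
1e5 attempts — an infeasible spec (e.g. seventeen 3 ms-separated delays in
a 49 ms range) errors loudly rather than degrading silently.

`oscillatory_fraction()` simulates each sampled configuration in dendritic
mode at 10 Hz for 200 s (2000 cycles), classifies it, and reports the
oscillatory fraction with an exact binomial 95% confidence interval.
Per-sample seeds are derived from the master seed by sample index, so
results are independent of execution order. Runs that come back
undetermined are re-simulated once at 3000 s: some limit cycles lock
slowly (we measured period-9 to period-462 loops that only fall within
tolerance after ~10^4 cycles), and several full periods must fit in the
post-burn-in window. Whatever remains undetermined is reported as such and
never counted as oscillatory.

For three dendrites with three synapses each, this procedure classifies
roughly a quarter to a third of random initial conditions as oscillatory
(seed-to-seed variation at n = 500 is a few percent) — the package's
operational, asymptotic criterion is conservative: it demands exact joint
recurrence over three full periods, counts slow-locking loops only if they
lock within 3000 s, and counts nothing transient. Looser readings of
"oscillatory" (e.g. visual inspection of weight trajectories over a ~100 s
window, or counting non-converged runs as oscillating) would land higher,
and the fraction is insensitive to the contract toggles we exposed
(nearest-only pairing, refractory pairing, integer-ms delays all give the
same or lower values). The classification settings are all exposed, so the
sensitivity of the fraction to the criterion can be explored directly.

## Numerical choices and degenerate inputs

* Threshold crossing is `v >= 1` (an effective weight of exactly 1 at a
  quiet membrane evokes a spike); the same rule defines "above threshold"
  in the sampler.
* The cutoff comparison `|Delta| <= 50` and refractory comparison use a
  1e-9 ms tolerance; spike offsets are quantized to 0.01 ms for signature
  comparison.
* Voltage carries across cycle boundaries (no artificial reset); at
  `tau = 20` ms the residual after 50 ms of silence is below `e^{-2.5}` of
  threshold, but it is still the difference between a 0.9 and a 1.0 jump
  landing a spike, so it is kept.
* Zero-cycle protocols, configs with orphan dendrites, non-positive
  delays or weights, and trajectories shorter than twice the burn-in all
  error with the violated invariant named.
* Simulations are deterministic; seeds exist only for sampling and are
  echoed into traces for provenance.

## Problem sizes in tests

The test suite validates the engine against the dense oracle on 50 random
configurations of up to 7 inputs for 2 s each, the pairing logic against
exhaustive enumeration on 25 random traces, preset asymptotics over
300–3000 s runs, and the ensemble machinery end-to-end at small n; the
full 500-sample ensemble estimate is exercised in the acceptance path.
These sizes were chosen so the whole suite completes in a few minutes
while every claim is still tested at a scale where failures would show.

## Known limitations

* The package models a single output neuron under strictly periodic,
  simultaneous stimulation; irregular stimulation, noise, inhibition,
  multi-layer or recurrent topologies are out of scope.
* The synthetic ensemble emulates random *initial conditions* of the
  stated architecture family, not biological variability: real inputs are
  not simultaneous, delays drift, and thresholds adapt. Passing tests
  show the dynamics of this idealised model, not predictions for cortical
  tissue.
* Initial weights of the figure presets are interpretations of
  colour-coded panels (see above); exact published trajectories are not
  reproducible bit-for-bit, only their narrated qualitative structure.
* The oscillatory fraction depends on the operational oscillation
  criterion; the package's asymptotic classifier is deliberately strict
  and documented, but it is one choice among several defensible ones.
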