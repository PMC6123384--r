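---
title: "Fixed-point event-driven spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-point event-driven spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefix)
```

## The model

`spikefix` simulates a digital spiking neural network fabric in which every
arithmetic operation is integer addition, saturation, or a bit shift. A
neuron is a vector of `k` state components `x = (x0, ..., x_{k-1})` (membrane
potential, synaptic currents, calcium, adaptive threshold, plasticity
modulator — the interpretation is free), updated once per tick (nominally
1 ms) by the difference equation

    x[t+1] = sat( x[t] + A ◇ x[t] + (Ξ[t] ∘ W) s[t] + η[t] + b )

where

* `A` is a matrix of *shift coefficients*: each entry is a signed power of
  two `±2^e` (`|e| ≤ 15`) or the exact-zero sentinel, so coupling a
  component into another costs one bit shift, never a multiplication;
* `s[t]` are the spikes delivered this tick, `W` their 8-bit weights
  (scaled by a per-component power-of-two gain), and `Ξ` a Bernoulli
  blank-out mask — multiplicative synaptic noise with a dyadic survival
  probability, nominally 1/2;
* `η` is additive zero-mean integer noise of programmable power-of-two
  variance, built as the sum of four uniform draws;
* `sat` clamps to the state width (16-bit by default), optionally with a
  per-component lower bound (used for rectifying error integrators).

A neuron spikes when component 0 reaches its threshold (`>=` comparison);
any component with reset enabled snaps to its reset value when it crosses
its own threshold; after a spike the membrane component is clamped at its
reset value for a programmable refractory period while the other components
keep evolving.

### The corrected shift and the leak operator

A plain arithmetic right shift of a two's-complement integer rounds toward
minus infinity, so `-1 >> k` is `-1` forever and small negative states
never decay to rest. `fx_shift()` instead truncates toward zero
(`sign(x) * (|x| >> k)`), which makes down-shifting `-2^{a'}` by `a > a'`
positions exactly zero. On top of it, `fx_leak()` adds a guaranteed
one-LSB decay: when a leak-signed coefficient's shifted magnitude truncates
to zero on a nonzero state, the increment is `-sign(x)`. This is the
weakest rule that makes "every state decays to exactly zero and stays
there" a theorem rather than a hope; without it any `|x| < 2^{-e}` would
stall permanently. Both properties are verified exhaustively in the test
suite.

### Counter-based randomness

Every stochastic draw — noise, blank-out, randomized rounding — is a pure
function of `(seed, purpose, id, tick)` through a 64-bit mixing function.
Nothing is stateful, so a simulation is reproducible bit-for-bit, can be
continued from a saved state exactly, and — because a draw never depends on
evaluation order — is invariant to how neurons are partitioned across
simulated cores. The hardware-style alternative (a stateful LFSR) is
deliberately not emulated; behavioural determinism and partition
invariance were judged more valuable than bit-compatibility with one
particular generator.

### The two-stage tick

Each tick: (1) every core integrates its neurons' dynamics and detects
threshold crossings, without touching synaptic input; barrier; (2) spikes
are routed — a spike emitted at tick `t` with axonal delay `d` is
accumulated at its targets during tick `t+1+d` and therefore first affects
their integration at `t+2+d`; external input events at tick `τ` behave as
if emitted by virtual neurons at `τ-1`; barrier; (3) every core
accumulates the deliveries due now into a double-buffered accumulator,
runs the plasticity engine, updates derived modulator components, and
applies conditional resets. Cores are simulated sequentially; the barriers
are semantic, not concurrent, and the result is independent of the
partition.

### Three-factor forward-table plasticity

The learning engine is pre-sensitive: all weight updates are triggered by
pre-synaptic events (or the expiry of a pre-synaptic timer), so only
forward rows of the synapse table are ever touched and one timer per
neuron suffices — O(N) memory independent of synapse count. When a pre
neuron fires, pending causal updates for its previous spike are committed
(each post spike pairs with the nearest pre spike at or before it), then
acausal updates are computed against each post neuron's last spike. The
kernel is an exponent staircase (exact for the linear mode; the
exponential mode decrements the shift exponent every half-decay step), and
the contribution at lag `dt` is the post neuron's modulator component
shifted by the kernel exponent — linear in the modulator, logarithmic in
the kernel, which is what an error-driven third factor requires. Updates
are clipped into the weight range after randomized rounding: the `r`
discarded low bits of an update are interpreted as an increment
probability, so arbitrarily small learning rates remain unbiased on 8-bit
weights.

Timer expiry is processed eagerly every tick. A lazy commit (waiting for
the next pre spike) can silently lose a pairing when a later post spike
outside the window overwrites the single post timer; with eager expiry the
engine reproduces brute-force nearest-neighbour pairing integer-exactly
whenever the post refractory period is at least the window length, which
the test suite checks on hundreds of random Poisson train pairs.

Two rule variants exist beyond timing-based pairing: a `state` rule that
commits the (gated, shifted) modulator on every pre spike — used by the
error-modulated, membrane-gated classifier rule and by the
voltage/calcium sequence rule — and an optional boxcar gate that blocks
updates unless a designated post component lies within a band.

## Tunable parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| state width | bits | 16 | demonstration networks store all states in 16 bits |
| weight range | — | [-128, 127] | 8-bit synapses |
| shift exponents | log2 | [-15, 15] | coefficient grammar of the fabric |
| blank-out probability | — | 1/2 | multiplicative sampling noise; 1/2 works best as a scaling constant |
| rounding bits `r` | bits | rule-specific (6 for the classifier) | unbiased sub-LSB learning rates |
| refractory vs. STDP window | ticks | refractory ≥ window | makes nearest-neighbour pairing exact |

## The demonstration models

**Generalized integrate-and-fire behaviours.** The adaptive-threshold
neuron family maps onto the fabric with component 0 as the
membrane-minus-threshold variable (spiking against a constant threshold),
linear adaptation currents coupled through snapped power-of-two
coefficients, and spike-triggered additive current increments realized as
self-synapses (hardware resets are constant-valued, so an increment is a
delivery, not a reset). Six presets — tonic, phasic, mixed, class I,
class II, tonic-burst — are classified by statistics of their spike
trains (ISI regularity, burst bimodality, rate-versus-current continuity).
Continuous-parameter trajectories are *not* reproduced; the acceptance
surface is the qualitative behaviour class, because all real-valued
constants are rounded to powers of two.

**Neural fields.** 100 one-component units, no reset and no refractory
period, so a unit emits on every tick it sits above threshold — the
discrete Heaviside activation of the continuum field equation. The lateral
kernel is a difference of Gaussians quantized onto the 8-bit grid with the
uniform quantizer `Q(r) = Δ⌊r/Δ + 0.5⌋`; external Poisson channels drive
the sheet one-to-one. The `bump` preset uses strong local excitation with
broad inhibition (self-sustained activity persists 2100 ticks after input
removal); `selection` weakens excitation so mutual inhibition leaves
exactly one of two stimulated regions active; `tracking` weakens
excitation below self-sustainment and shifts the excitatory Gaussian by
one unit, so the activity profile follows a displaced input patch within a
couple of leak time constants.

**Event-driven random back-propagation.** A 16-10-2 feed-forward spiking
classifier with stochastic synapses. Spiking error pairs (positive and
negative rectifying integrators per class, floor at zero, reset to zero)
compare prediction spikes against a regular label train; prediction
modulators receive one-to-one error feedback, hidden modulators a fixed
random zero-sum projection of the error spikes. Weight updates are the
`state` rule: modulator × boxcar(membrane) on every pre spike, 8-bit
weights, `r = 6` rounding bits, and updates disabled during the first 400
ticks of each 1500-tick presentation so stimulus transitions are not
learned. On the synthetic two-class Poisson rate task the training error
falls to zero within the first fifth of 500 presentations and frozen
evaluation accuracy reaches 100% on every seed tested.

**Event-based RBM with event-driven contrastive divergence.** 16 pixel
units and 2 one-hot class units bidirectionally connected to 100 hidden
units through a *shared* weight store, so weight symmetry is exact at
every tick by construction rather than by maintenance. Two modulatory
channels alternate the modulator sign between a clamped data phase
(logit-scaled on/off currents delivered as dense jittered event trains,
plus membrane noise) and a free-running reconstruction phase seeded by the
data state; the pair rule uses a symmetric window with positive sign on
both sides (a correlation window — the phase sign lives in the modulator)
and applies updates even for blanked-out deliveries, since dropped spikes
are valid samples of the stochastic synapse.

**Sequence learning.** 100 input channels onto 5 four-component neurons:
membrane, calcium (a spike-count trace incremented through a
self-synapse), a comparator component equal to +8 above the membrane
threshold and -2 below it, and a modulator adding a homeostatic term that
drives calcium toward its set point. Every input spike changes its weight
by the post modulator, gated to the voltage band above the reset value.
After training on a repeating spike pattern embedded in rate-matched
noise, all five outputs fire at least 3× (typically far more) faster
inside pattern windows than in noise segments, evaluated with frozen
weights on fresh input. This holds on the demonstration seed and on most
pattern draws; occasional draws fall into an anti-selective fixed point
(the reset that follows each pattern-evoked spike coherently depresses
late-pattern inputs), a known fragility of threshold-gated unsupervised
temporal learning that the voltage gate reduces but does not eliminate.

## Design choices where the design was genuinely open

* **Operand convention.** The shift operator's first argument is always
  the exponent; the modulated update shifts the *modulator* by the
  *kernel* exponent. The alternative (shifting a kernel amplitude by a
  modulator-derived exponent) is retained behind the `mode` switch of the
  kernel configuration but is not the default, because error-driven
  learning requires updates linear in the signed modulator.
* **Overflow policy.** All state arithmetic saturates at the declared
  width; nothing wraps. Accumulators are 32-bit and saturate too.
* **Refractory clamp.** Only component 0 is clamped during the refractory
  period; other components keep evolving. The alternative (clamping the
  whole vector) would freeze synaptic currents and modulators, which the
  learning rules need.
* **Tie between causal and acausal at lag 0.** A post spike in the same
  tick as a pre spike is paired causally (lag 0) and not acausally;
  acausal lags start at 1.
* **Modulator sampling time.** The modulator is read at the tick an update
  is committed, not at the tick of the paired spike.
* **Homeostatic sign of the sequence rule.** The homeostatic term is
  implemented as `+η_h(Ca_target − Ca)` — potentiation is pushed up when
  the neuron is below its activity set point — with the sign exposed as a
  parameter. Read literally, the printed form of the rule has the opposite
  sign, which de-stabilizes rather than regulates; the implemented sign is
  the one under which the homeostasis description is true.
* **Subtractive error reset.** Rectifying error integrators reset to zero
  on spiking (the fabric's resets are constant-valued) and are floored at
  zero by a per-component lower bound.

## What the synthetic generators emulate — and what they do not

`poisson_trains()` approximates Poisson processes as Bernoulli-per-tick
draws (exact to within 2% at the rates used). `embedded_pattern_trains()`
draws the repeating pattern conditioned on the exact expected spike count,
so pattern and noise segments match in rate by construction and detection
must rely on spike timing; real sensory streams are neither
rate-stationary nor exactly repeating, so passing tests here demonstrate
the learning mechanics, not robustness to natural statistics.
`bars_stripes()` is the canonical 32-pattern 4×4 set. All generators are
pure functions of their seed.

## Numerical choices

Problem sizes were chosen at desk scale: the behaviour battery runs six
single-neuron simulations of 2000–3000 ticks plus a 12-point
rate-versus-current sweep; the field demonstrations use 100 units for
2500 ticks; partition invariance is checked on a 200-neuron random network
for 5000 ticks on 1, 2 and 4 cores; the classifier trains on 500
presentations of 1500 ticks; the RBM on 50 epochs of 32 presentations; the
sequence learner on 600 pattern repetitions. The oracle-equivalence check
uses 200 random train pairs of 10^4 ticks. Degenerate inputs are defined:
zero-tick runs return empty records, empty synapse tables are valid, the
zero coefficient sentinel contributes nothing, and `r = 0` rounding is the
identity.

## Known limitations

* The mapping from continuous-parameter neuron models is qualitative:
  coefficients are snapped to powers of two and spike-triggered current
  increments arrive with the two-tick delivery latency of a self-synapse.
* The nearest-neighbour pair counter equals exact STDP only when the post
  refractory period reaches the window length; below that it is the
  documented approximation.
* Event-driven contrastive divergence learns feature structure on
  bars-and-stripes, but its classification error at the 32-sample,
  50-epoch scale remains near chance in this implementation. The
  phase-resolved update decomposition in the tests' companion analysis
  shows why: with clamped units firing near the refractory ceiling, the
  windowed pair counter saturates at about one pairing per pre spike and
  under-counts data-phase co-activity relative to the causally generated
  co-spiking of the free-running phase, so the data/reconstruction
  contrast cannot be balanced in its mean and its structure
  simultaneously. The equivalence of event-driven and standard
  contrastive divergence holds for Poisson pre/post statistics, which the
  clamped regime violates. Hand-built row/column detector weights reach a
  few percent error under the same spiking readout, so the substrate
  supports the task; the gap is specific to the estimator. Weight
  symmetry, the sampling mechanics and the phase machinery are exact and
  fully tested.
* The simulator is behavioural: router microarchitecture, packet formats,
  weight-memory compression and clock-level timing of a hardware
  realization are out of scope.
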