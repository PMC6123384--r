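# spikefix

`spikefix` is a desk-scale software model of a multiplier-less, fixed-point,
event-driven spiking neural network fabric with embedded three-factor
learning — the kind of architecture used in digital neuromorphic processors,
where every state is a saturating 16-bit integer, every coefficient is a
signed power of two applied as a bit shift, synaptic weights are 8 bits with
Bernoulli blank-out, and all learning happens online from spike events. It
is intended for researchers prototyping event-driven learning rules under
realistic hardware constraints, and for reproducing the behaviour of such
fabrics without access to one.

## The model in brief

Neurons are vectors of `k` state components updated once per tick:

    x[t+1] = sat( x[t] + A ◇ x[t] + (Ξ[t] ∘ W) · s[t] + η[t] + b )

`A` holds shift coefficients (`±2^e`, `|e| ≤ 15`, or exactly zero); `◇` is a
corrected signed shift that truncates toward zero, so `-2^{a'} ◇ a = 0` for
`a' < a` where a plain arithmetic shift would leave `-1`; a leak contribution
that truncates to zero on a nonzero state decays it by one LSB instead, so
every state reaches rest exactly. `Ξ` is per-delivery Bernoulli blank-out,
`η` programmable integer noise, and spikes emitted at tick `t` reach their
targets at `t+1+delay`. Learning is a pre-sensitive, forward-table,
nearest-neighbour spike-timing rule with a third factor: the update at lag
`dt` is the post neuron's modulator state shifted by the kernel exponent,
clipped into the 8-bit range after randomized rounding (the discarded low
bits act as an increment probability, keeping tiny learning rates unbiased).
All randomness is counter-based — a pure function of `(seed, id, tick)` — so
runs are reproducible and bit-identical under any partition of neurons onto
cores.

Five demonstration models ship with the package: the six classic
generalized integrate-and-fire firing behaviours, Amari neural-field bump /
selection / tracking dynamics, an event-driven random back-propagation
classifier, an event-based RBM trained by event-driven contrastive
divergence, and a voltage/calcium sequence-learning rule.

## A worked example

A leaky neuron driven over threshold, and the corrected shift itself:

```r
library(spikefix)

fx_shift(-3, -4)   # -4 * 2^-3 -> 0   (floor(-4/8) would be -1)
#> [1] 0

g   <- neuron_group(k = 1, A = matrix(-2^-4), b = 40L, theta = 500L,
                    Xr = 0L, refractory = 4L)
cfg <- run_config(list(g), group_of = 1L)
res <- sim_run(cfg, 200, seed = 1)
res
#> <sim_result> 200 ticks, 7 spikes, 0 SynOps (seed 1)
head(res$raster$tick)
#> [1]  22  49  76 103 130 157
```

The neuron integrates its bias against the `2^-4` leak, crosses threshold
at tick 22 and then fires every 27 ticks (23 ticks of charging plus the
4-tick refractory period); with no synapses there are no synaptic
operations (SynOps). The demonstration models follow the same pattern:

```r
m <- field_metrics(run_field("bump", seed = 1))
round(m$ratio)        # in-band vs out-of-band activity after input removal
#> [1] 599714285714    # outside activity is exactly zero

s <- seqlearn_demo(seed = 1)
round(s$pattern_rate) # Hz inside pattern windows, per output neuron
#> [1] 20 20 20 20 20
round(s$noise_rate, 1)
#> [1] 0.0 0.3 0.2 0.2 0.0
```

A thin command-line front end is installed at `inst/cli/spikefix`
(`spikefix demo field --preset bump --seed 1 --out out/`, `spikefix run`,
`spikefix validate`).

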