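---
title: "Unsupervised pattern discrimination in a plastic spiking reservoir: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised pattern discrimination in a plastic spiking reservoir: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedisc)
```

## The scientific problem

Biological networks learn new patterns while retaining old ones, despite
every synapse being plastic at all times.  `spikedisc` simulates a
three-layer spiking network that exhibits this behaviour: a *source* layer
of Poisson spike generators driven by binary images, a recurrent
excitatory-inhibitory *reservoir* that mixes the input nonlinearly, and a
small *sink* layer of readout neurons whose banded firing-rate vectors form
discrete codes.  Excitatory synapses follow an anti-symmetric
spike-timing-dependent plasticity (STDP) rule, inhibitory synapses a
symmetric one, and both stay on forever.  The claim under study is that the
interaction of the two rules (i) balances excitatory and inhibitory
currents, (ii) sculpts sparse receptive fields in the source-to-reservoir
weights, and (iii) yields readout codes that discriminate the input
patterns without any supervision — and keep doing so as new patterns
arrive.

## Neuron and synapse model

Each neuron is a conductance-based leaky integrate-and-fire unit,

$$\tau_m \frac{dV}{dt} = (V_{rest} - V)
  + (E_{ex} - V)\,\tilde g_{ex} + (E_{inh} - V)\,\tilde g_{inh},$$

advanced by explicit Euler at `dt` = 1 ms, with threshold
$V_T = -54$ mV, reset $V_{reset} = -60$ mV, $\tau_m = 20$ ms, and reversal
potentials 0 / −80 mV.  Conductances integrate presynaptic spikes as delta
pulses weighted by the synaptic weight and decay with
$\tau_{AMPA} = 40$ ms (excitation) and $\tau_{GABA} = 50$ ms (inhibition);
the decay uses the same Euler discretization as the membrane
($g \leftarrow g(1 - dt/\tau)$), with exact exponential decay available via
`exact_decay = TRUE`.

**Units.**  Synaptic weights are quoted on a nominally-nS scale
($g^E_{max} = 0.3$, $g^I_{max} = 0.2$, initial weights uniform on
$(0, 0.1)$ or $(0, 0.2)$), but the membrane equation above is unitless.
The package resolves this by expressing conductances in units of the leak:
$\tilde g_{ex} = g_{ex} / g_{leak}$ and
$\tilde g_{inh} = g_{inh} / g_{leak,gaba}$ with defaults 8 and 3.2.  The
two constants were calibrated once, jointly, so that the model reproduces
its qualitative operating regime — a balanced state at a few tens of Hz
with sparse receptive fields, and a fast unbalanced state when inhibitory
plasticity is disabled — and are fixed thereafter.  The GABA unit is 2.5×
the AMPA unit, reflecting the larger unitary conductance of GABA$_A$
synapses and the ~3× smaller inhibitory driving force near threshold.
Taken literally (both constants 1) the printed weight scale saturates every
neuron within milliseconds, so some such conversion is unavoidable.

Three further dynamical ingredients proved necessary and are part of the
model as implemented, each config-exposed:

* **Absolute refractory periods** — 5 ms for excitatory neurons, 4 ms for
  the (fast-spiking) inhibitory populations.  Purely reset-based dynamics
  lock the network into a deterministic synchronous limit cycle in which
  every neuron fires once per population cycle; rates then carry no pattern
  information at all.  The inhibitory ceiling also matters for the
  plasticity ablation: without it, a fixed-inhibition network simply
  compensates weak weights with higher interneuron rates.
* **Axonal conduction delays** — each neuron's outgoing spikes are
  delivered with a delay drawn uniformly from 1–10 ms (`delay_max`).  A
  single shared delay synchronizes the network for the same reason.
* **Background afferents** — every reservoir and sink neuron receives an
  independent 500 Hz Poisson background with weight 0.1 (`f_bg`, `w_bg`),
  standing in for the afferents a real circuit receives from outside the
  modelled layers.  This keeps the network in the fluctuation-driven
  (asynchronous irregular) regime where firing rates are sensitive to input
  differences, and prevents absorbing silent states: a silenced readout
  whose inhibition is frozen at its ceiling can never recover otherwise,
  because both plasticity rules only update on spikes.

## Plasticity

Excitatory synapses change by
$\Delta w = A^+ e^{\Delta t/\tau^+}$ for causal pairs
($\Delta t = t_{pre} - t_{post} < 0$) and
$-A^- e^{-\Delta t/\tau^-}$ otherwise, with $A^+ = 0.005$,
$\tau^\pm = 20$ ms and $A^- = \beta A^+ \tau^+/\tau^-$.  For the input and
recurrent classes $\beta = 1.05$, a slight depression bias that drives
synaptic competition and the characteristic bimodal weight distribution.
Inhibitory synapses change symmetrically: potentiation
$B^+ e^{-|\Delta t|/\tau_i}$ for near-coincident pairs
($|\Delta t| \le \tau_i = 10$ ms), depression $-B^- e^{-|\Delta t|/\tau_i}$
for distal ones ($B^+ = 0.0015$, $B^- = 0.0003$).  Note that because both
branches decay with the same $\tau_i$ and $B^+/B^- = 5$, the inhibitory
rule is potentiation-dominant at *any* firing rate: inhibitory weights
ratchet toward $g^I_{max}$, and the balanced state is set by the ceiling
$N_I c \, g^I_{max} \tau_{GABA}$ of the inhibitory budget rather than by a
rate fixed point.  All weights are hard-clipped to $[0, g_{max}]$ of their
class, and connectivity is fixed (no structural plasticity).

**Pairing scheme.**  The curve above says what a pair of spikes does; a
scheme must decide which pairs count.  Both standard schemes are
implemented, selectable per projection (`estdp_pairing`):
nearest-neighbour (each update pairs against the single stored last spike)
and trace-based all-to-all (each neuron carries exponentially decaying
pre/post traces that sum over all past spikes).  The default uses
all-to-all on the feed-forward classes (source→reservoir, E→I,
reservoir→readout, readout→sink-I) and nearest-neighbour on recurrent E→E.
The reason is quantitative: under nearest-neighbour pairing the expected
drift is dominated by the pre/post *rate ratio* — a synapse whose
presynaptic rate exceeds its postsynaptic rate depresses regardless of
causal structure — which zeroes exactly the informative synapses (receptive
fields come out aligned with the patterns only at chance level).
All-to-all pairing is rate-neutral (drift
$\lambda_{pre}\lambda_{post}(A^+\tau^+ - A^-\tau^-)$ plus a
causality bonus), so genuinely driving synapses win.  On recurrent E→E,
however, all-to-all pairing lets reverberating loops potentiate themselves
into saturation; nearest-neighbour pairing bounds that positive feedback.
The inhibitory rule always uses nearest-neighbour pairing.

**Readout balance.**  The reservoir→readout and the other purely
feed-forward classes (E→I, readout→sink-I) use a potentiation-favourable
balance `beta_readout` = 0.9.  With the depression-biased $\beta = 1.05$
those pathways cannot reach their described end state (uniform saturation
at $g_{max}$): the rate-neutral baseline is negative and the causal bonus
of a readout integrating ~60 presynaptic neurons is spread too thin.  A
balance just below 1 lets causally driven feed-forward synapses saturate
while leaving the competitive dynamics of the input and recurrent classes
untouched.

## Architecture and presets

The full-size model has $K = 900$ source neurons (30×30 images), 200
excitatory + 50 inhibitory reservoir neurons, and 8 readout neurons;
connection probabilities are 20% source→reservoir, 40–50% within the
reservoir, 30% reservoir→readout, and all-to-all between the readout and
its inhibitory pool.  The sink inhibitory pool size is not part of the
published architecture; the package uses `M_I = 6`, the smallest pool in
our exploration that regulates the readout into its pattern-sensitive range
(smaller pools either let the readout saturate at the refractory ceiling or
collapse it into a single winner).

The `"desk"` preset scales the network to 15×15 images ($K = 225$), 100+25
reservoir neurons and $J = 5$ probe repeats, keeping every dynamical
constant identical.  It exists so that training experiments run in seconds;
all package tests and the acceptance script use it.  Note that the readout
samples 30% of the reservoir in both presets: preserving the sampling
*fraction*, not the in-degree, is what preserves readout selectivity,
because each readout neuron's code symbol derives from how its random
subsample of the reservoir deviates from the population mean.

## Input encoding and protocol

Binary patterns are flattened row-major, one pixel per source neuron.
Black pixels fire Poisson at 90 Hz (Bernoulli $f\,dt$ per step); at each
presentation a fresh random 10% of the white-pixel neurons fires at 10 Hz
(image noise).  Training presents patterns in random order for
exponentially distributed durations (mean 30 ms, truncated at one step).
Probes freeze all plasticity, present every pattern $J$ times for
$d = 1.4$ s in a fixed sequence, and restore the training state afterwards
(probe time does not count toward training time).

The synthetic pattern generator (`flag_patterns`) composes horizontal and
vertical bars, blocks, diagonals and discs into binary images with bounded
pairwise overlap.  It emulates the *statistics* of flag-like training
images — a handful of overlapping rectilinear features per pattern — not
any specific published bitmaps (which were never released).  Training sets
use stripe/block motifs; "new" sets add diagonal and disc features.
Passing tests on these fixtures shows the machinery discriminates
structured binary inputs of this kind; it does not certify behaviour on
natural images or on patterns with graded intensities.

## Readout codes and the discriminability index

For one probe presentation the readout count vector is banded into symbols
by its ratio to the maximal count: ternary default 2 for ratios in
$[0.9, 1]$, 1 for $[0.4, 0.9)$, 0 below.  The printed top band excludes
ratio 1.0, which would exclude the maximal neuron itself; the package
includes it.  All-zero counts give the all-zero code.  For other coding
levels: binary thresholds at 0.5, higher levels use a fixed top band at
0.9 with equal interior bands (override via `edges`).

Per pattern, the *prototype* is the modal code over the $J$ repeats (ties
and no-repeat cases broken uniformly at random).  The inter-pattern
distance $D_{inter}$ sums, over readout neurons, the mean pairwise symbol
disagreement between prototypes; the intra-pattern distance $D_{intra}$
averages pairwise code distances within patterns (unweighted mean across
patterns).  Separability $\varepsilon = 1 - D_{intra}/D_{inter}$ (guarded
to 0 when $D_{inter} = 0$), uniqueness $\gamma$ = (#unique prototypes)/P,
and $DI = \varepsilon \gamma$.

The closed-form maximum of $D_{inter}$ is provided in two variants.
`method = "printed"` follows the published parity-cased expression whose
worked value at $P=15, C=2, M=8$ is $15 \cdot 8/(2\cdot14) = 4.2857$.
`method = "exact"` computes the true combinatorial maximum from the most
even partition of $P$ patterns into $C$ symbol groups,
$(P^2 - \sum_c n_c^2)/(P(P-1))$ per neuron, which matches exhaustive
enumeration for every instance (the tests verify this for
$P \le 5, C \le 3$).  The two disagree whenever $P/C$ is not an integer —
at the worked point the exact maximum is 4.2667 — because the printed
derivation assumes an exactly equiprobable symbol assignment.

## Fano-factor selection of the test duration

The test duration $d$ is chosen where the Fano factor (variance/mean of
readout spike counts over repeated trials) is minimal.
`fano_factor_curve()` computes, by default, the per-neuron Fano factor over
trials, averaged across neurons and patterns.  The alternative of pooling
all $M \times trials$ counts per pattern before taking variance/mean
(`per_neuron = FALSE`) is also available, but in this implementation the
pooled statistic is dominated by the systematic rate differences *between*
readout neurons — precisely the heterogeneity that carries the code — and
therefore measures code structure, not trial reliability.  At desk scale
the per-neuron curve sits around 0.4–0.6 for $d$ between 0.6 and 2.2 s:
strongly sub-Poisson, consistent with refractory-regularized firing.

## Synaptic distance and back-tracing

Weight matrices are binarized at $0.7\,g^E_{max}$; the synaptic distance
$\phi$ between two snapshots is the normalized Hamming distance.  The
chance-level $\phi_{shuffled}$ permutes the later snapshot's entries
uniformly (preserving the number of strong synapses; 10 shuffles by
default), with closed-form expectation $p_1(1-p_2) + p_2(1-p_1)$ that the
tests verify by Monte Carlo.  The relative distance
$\phi_{rel} = |\phi - \phi_{shuffled}|/\phi_{shuffled}$ is reported as `NA`
when $\phi_{shuffled} = 0$ (no strong synapses — e.g. a fully saturated,
unchanging projection), matching its undefined status.

`backtrace_networks()` reconstructs, for one presentation, the *structural*
subgraph (reservoir neurons strongly connected to the maximally firing
readout neurons — those holding the top code symbol — plus strong recurrent
edges among them) and the *functional* graph (directed transitions: spikes
of one node followed by another within one STDP window, 20 ms by default;
raw counts are stored, normalization is left to rendering).

## Experiments

* `train_network()` — the fitting routine: training segments alternating
  with frozen DI probes; returns an `snn_fit` with
  `print`/`summary`/`coef`/`plot`/`predict`/`simulate` methods.
* `istdp_ablation()` — matched on/off pair from identical initial wiring;
  with inhibitory plasticity off (weights fixed at initialization) the
  reservoir runs hot (~2–3× the balanced rate at desk scale; the full-size
  contrast reported for this model is 120 vs 20 Hz), receptive fields wash
  out, and the DI collapses.
* `shuffle_connectivity()` / `shuffle_controls()` — six rewiring controls
  preserving weight multisets and in-degrees; shuffling the learned
  source→reservoir wiring (case 1, and case 6 which contains it) destroys
  discrimination while shuffling the saturated readout projection (case 5)
  does not, plus the readout-code symbol-permutation control.
* `stability_plasticity()` — two-phase protocols (`old+new`, `new-only`,
  `old-only`) with DI probed on the pattern union and $\phi_{rel}$ tracked
  against the phase-1 endpoint.
* `parameter_sweep()` — DI as a function of coding level, readout count, or
  connectivity.

## Problem sizes and numerical choices

The package's standard experiment (used by the tests and the acceptance
script) is the desk preset with 8 training patterns, 5 replicate seeds,
300-second training phases (200 s in the test suite), probes every 50–75 s,
and $J = 5$ probes of 1.4 s.  DI trajectories plateau within the first
~100 s at this scale.  All randomness flows through R's RNG, so a single
`set.seed()` reproduces a run bit-for-bit; probes are side-effect-free.
Simulation chunks lose spikes in flight at their boundaries (at most
`delay_max` ms per chunk boundary, once per probe interval) — a deliberate
simplification with no measurable effect at the cadences used.

Degenerate inputs are handled explicitly: all-zero counts give the all-zero
code, $D_{inter}=0$ guards the DI to 0, $\phi_{rel}$ is `NA` at zero
chance-level distance, empty schedules return empty records, and non-finite
membrane potentials abort the run.

## Known limitations

* The desk-scale operating point differs quantitatively from the full-size
  report: the balanced reservoir sits near 30–35 Hz rather than 20 Hz, the
  ablated network near 70–90 Hz rather than 120 Hz, the net-to-excitatory
  current ratio is ~0.4 rather than near zero, and the strong-synapse
  fraction of the learned receptive fields is ~15–20% rather than ~5%.
  The qualitative contrasts (balanced vs runaway, sparse vs washed-out
  receptive fields, high vs collapsed DI) are robust across seeds.
* The unit reconciliation ($g_{leak}$, $g_{leak,gaba}$), refractory
  periods, delays, background drive, and the feed-forward STDP balance are
  this package's modelling choices where the published description is
  silent or dynamically unattainable as printed; each is config-exposed and
  revertible.
* The supervised-learning extensions sketched for this architecture
  (label-driven sink stimulation) are out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg  <- snn_config("desk")
pats <- flag_patterns(8, cfg$image_size, seed = 11)
fit  <- train_network(build_network(cfg, seed = 1), pats,
                      total_s = 300, probe_every_s = 60, seed = 3)
fit                      # DI trajectory, rates, balance
plot(fit, "di")
summary(fit$net)         # per-projection weight statistics
predict(fit)             # a fresh frozen probe
shuffle_controls(fit$net, pats, cases = c(1, 5))
```
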