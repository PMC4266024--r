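# spikedisc

Unsupervised pattern discrimination in a plastic spiking reservoir network.

`spikedisc` simulates a three-layer network of conductance-based leaky
integrate-and-fire neurons — a source layer of Poisson generators driven by
binary images, a recurrent excitatory–inhibitory reservoir, and a small
sink layer of readout neurons — in which *every* synapse is plastic at all
times.  Excitatory synapses follow the anti-symmetric additive STDP rule

&nbsp;&nbsp;Δw = A⁺ e^{Δt/τ⁺} (Δt < 0), &nbsp; −A⁻ e^{−Δt/τ⁻} (Δt ≥ 0),
&nbsp; Δt = t_pre − t_post,

with a slight depression bias β = A⁻τ⁻/(A⁺τ⁺) = 1.05; inhibitory synapses
follow the symmetric rule Δz = B⁺e^{−|Δt|/τ_i} for near-coincident pairs
(|Δt| ≤ τ_i) and −B⁻e^{−|Δt|/τ_i} otherwise.  Inhibitory plasticity
balances excitatory and inhibitory currents; excitatory plasticity carves
sparse receptive fields into the source→reservoir weights; the readout's
ternary firing-rate codes (per-neuron symbols from banded count ratios,
bands [0, 0.4), [0.4, 0.9), [0.9, 1]) discriminate the inputs without
supervision.

Discrimination is quantified by the **Discriminability Index**

&nbsp;&nbsp;DI = ε · γ, &nbsp; ε = 1 − D_intra / D_inter, &nbsp;
γ = #unique prototype codes / P,

where D_inter is the mean pairwise Hamming-type distance between the modal
("prototype") codes of the P patterns, summed over readout neurons, and
D_intra is the within-pattern code variability over J repeated frozen
probes.  The package also provides the closed-form maximum of D_inter, the
Fano-factor selection of the probe duration d, binarized synaptic-distance
diagnostics (φ, φ_shuffled, φ_rel), receptive-field extraction,
structural/functional back-trace graphs, connectivity-shuffle controls,
and stability–plasticity (old/new pattern) protocols.

The millisecond-resolution simulation loop is C++ (Rcpp); everything is
driven from R and is bit-reproducible from a single `set.seed()`.

## A worked example

```r
library(spikedisc)

cfg  <- snn_config("desk")                       # 15x15 images, 125 reservoir neurons
pats <- flag_patterns(8, cfg$image_size, seed = 11)
fit  <- train_network(build_network(cfg, seed = 1), pats,
                      total_s = 300, probe_every_s = 60, seed = 3)
fit
#> <snn_fit>
#>   trained 300 s (both plasticity) on 8 patterns; t = 300.3 s
#>   DI: final 0.728, mean 0.827 over 5 probes
#>   reservoir rate 32.0 Hz; |I_net|/I_ex = 0.386 (final windows)
```

The discriminability index rises to a sustained plateau around 0.8–0.9
within the first two minutes of simulated training: the readout codes are
almost perfectly repeatable (high separability) and distinct across
patterns (uniqueness near 1).  The reservoir settles into a balanced state
at a few tens of Hz in which inhibitory currents track excitatory ones.
Disabling inhibitory plasticity (`plasticity = "no_istdp"`, inhibitory
weights frozen at initialization) drives the same network to 2–3× higher
rates, washes out the receptive fields and collapses the DI:

```r
off <- train_network(build_network(cfg, seed = 1), pats, total_s = 300,
                     probe_every_s = 60, plasticity = "no_istdp", seed = 4)
c(on = mean(fit$di_series$DI), off = mean(off$di_series$DI))
#>        on       off
#> 0.8267607 0.3429794
```

Useful follow-ups: `plot(fit, "di")`, `summary(fit$net)` (per-projection
weight statistics), `receptive_field(fit$net, j)` (image-shaped learned
weights of reservoir neuron j), `shuffle_controls(fit$net, pats)`
(rewiring controls), `stability_plasticity(...)` (old/new two-phase
protocols), and `fano_factor_curve(fit$net, pats, d_grid = ...)`.

A thin command-line wrapper for shell use lives at
`inst/cli/spikedisc.R` (`train` / `test` / `shuffle` subcommands).

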