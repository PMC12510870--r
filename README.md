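# cryoconsensus

Consensus analysis of cryo-EM conformational landscapes.

Heterogeneity-analysis methods (latent-variable map decoders,
deformation-field models, …) summarize each particle image of a cryo-EM
data set as a low-dimensional latent vector — a *conformational landscape*.
Two methods run on the same particles produce landscapes in unrelated
coordinate systems, so there is no direct way to ask where the methods
agree, which particles they disagree on, or what a region of one landscape
corresponds to in another. `cryoconsensus` answers these questions for R
users working with exported landscape matrices (CSV/TSV/NPY); it consumes
no images, maps, or particle stacks.

## Method

For `N` landscapes `X^1 … X^N` over the identical ordered particle set,
a multi-autoencoder (one encoder `E_n` and decoder `D_n` per space, three
1,024-unit ReLU layers each, linear bottleneck of dimension
`d = min(dim_n)` by default) is trained with the four-term objective

    L = Σ_{n,m} Σ_i ‖x_i^n − D_n(E_m(x_i^m))‖²   (cross-space reconstruction)
      + Σ_{n,m} Σ_i ‖E_n(x_i^n) − E_m(x_i^m)‖²   (L1, latent pairing)
      + Σ_n stress(d_ij(X^n), d_ij(E_n(X^n)))     (L2, Sammon-style distance preservation)
      + Σ_{n,m} W₁(D(E_n(X^n)), D(E_m(X^m)))      (L3, distance-distribution Wasserstein)

optimized by Adam (lr `1e-5`, batch 1,024) with sequential per-decoder
update steps. The trained bottleneck is a *consensus space* in which
corresponding particles from different methods coincide; from it the
package derives per-particle **consensus errors** (mean pairwise distance
between a particle's projections — do the methods agree on this
particle?), **representation errors** (`‖x_i^n − D_n(E_m(x_i^m))‖` — how
well is space `n` recovered from space `m`?), and **cross-landscape
conversion** `decode(to, encode(from, x))`.

The **consensus set** — the particles on which the methods statistically
agree — is found by ranking particles by consensus error and sweeping a
cutoff `K`: the top-`K` projections from two spaces are compared with a
sliced Wasserstein distance (κ = 100 shared random projections) under a
label-permutation null (100 randomizations); the largest `K` whose p-value
stays ≥ 0.05 defines the selection.

A seeded synthetic-landscape generator with planted ground truth
(discordant particles, method-exclusive clusters) makes the whole pipeline
testable without external heterogeneity software.

## Worked example

Simulate two landscapes with 10 % planted discordant particles, merge
them, and select the consensus set:

```r
library(cryoconsensus)

cfg <- simulation_config(num_particles = 1000, space_dims = c(2, 2),
                         noise_sigma = 0.05, discordant_fraction = 0.10,
                         discordant_displacement = 1, seed = 102)
sim <- generate_landscapes(cfg)
sim$set
#> <landscape_set: N=2 spaces, 1000 particles, dims (2, 2)>

net <- build_network(network_spec(sim$set$dims, hidden_width = 64, seed = 11))
fit <- train(net, sim$set,
             train_config(learning_rate = 1e-3, batch_size = 256,
                          epochs = 15, seed = 5))
fit
#> <train_result: 15 epochs; final epoch-mean total loss 988.158>

mapping <- map_to_consensus(fit$net, sim$set)
mapping
#> <consensus_mapping: 1000 particles, 2 spaces, latent dim 2; median consensus error 0.1826>

# planted discordant particles are ranked to the bottom:
mean(mapping$consensus_error[sim$truth$discordant]) /
  mean(mapping$consensus_error[!sim$truth$discordant])
#> [1] 7.609354

sel <- threshold_sweep(mapping, sw_config(kappa = 100, seed = 1),
                       K_grid = seq(100, 1000, by = 100))
sel
#> <consensus_selection: K* = 800 of 10 tested K values (alpha = 0.05); 800 particles kept>
```

The selection keeps 800 of 1,000 particles — the planted 10 % discordant tail
(and the fuzzy boundary around it) is excluded, and `sel$sweep` holds the full `(K, d_obs, p_value)`
table. `convert(fit$net, 1, 2, x)` then carries coordinates from
landscape 1 into landscape 2's frame.

The same workflow is available from a shell via the shipped CLI
(`system.file("cli", "cryoconsensus", package = "cryoconsensus")`) with
`simulate`, `train`, `map`, `filter`, and `convert` subcommands.

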