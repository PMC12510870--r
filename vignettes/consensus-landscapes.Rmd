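---
title: "Merging cryo-EM conformational landscapes into a consensus latent space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging cryo-EM conformational landscapes into a consensus latent space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoconsensus)
```

## The problem

Heterogeneity-analysis methods for cryo-EM (latent-variable map decoders,
deformation-field models, and their relatives) each summarize the
conformational state captured by every particle image as a low-dimensional
latent vector, yielding a *conformational landscape*: one row per particle,
one column per latent dimension. Different methods applied to the same
particle stack produce landscapes that live in unrelated coordinate systems,
with different dimensionalities, scales, and distortions — so there is no
direct way to ask whether two methods agree about a given particle, or to
carry an interesting region of one landscape over to another method.

This package addresses both questions by learning a single *consensus*
latent space into which every input landscape is encoded, together with
per-particle agreement metrics and a statistical procedure that selects the
subset of particles on which the methods demonstrably agree.

## The model

For `N` input landscapes `X^1 … X^N` over the identical ordered particle
set, the network holds one encoder `E_n` and one decoder `D_n` per space.
Each encoder is three fully connected layers of 1,024 ReLU units followed by
a linear bottleneck layer of dimension `d`; each decoder mirrors this,
ending in a linear layer back to its space's dimensionality. By default `d`
is the minimum input dimensionality, so no encoder is forced to invent
information its input does not carry; the user can override it.

Training minimizes the sum of four terms, evaluated per mini-batch:

* **Reconstruction (representation) loss** —
  `sum_{n,m} sum_i || x_i^n - D_n(E_m(x_i^m)) ||^2`.
  Every space must be recoverable from every space's encoding of the same
  particle, self-pairs included. After training, the per-particle residual
  norms are the *representation errors*.
* **Latent pairing loss `L1`** —
  `sum_{n,m} sum_i || E_n(x_i^n) - E_m(x_i^m) ||^2`.
  Reconstruction alone happily parks each space in its own corner of the
  bottleneck; `L1` pulls the encodings of the same particle from different
  spaces onto one another, which is what makes the bottleneck a *consensus*
  space. The double sum runs over ordered pairs exactly as the objective is
  defined; the resulting factor of two is absorbed by the optimizer.
* **Distance-preservation stress `L2`** — for each space, a Sammon-style
  normalized stress between the pairwise-distance matrices of the input
  batch and of its encoding,
  `[sum_{ij} (d_ij(X) - d_ij(Z))^2 / d_ij(X)] / [sum_{ij} d_ij(X)]`.
  This anchors the local geometry of each input space in the consensus
  space, preventing the pairing loss from collapsing structure. Pairs with
  `d_ij(X) = 0` (duplicate inputs) are excluded — the stress is undefined
  there and duplicates carry no geometric information.
* **Distance-distribution loss `L3`** — the 1-D Wasserstein distance
  between the distributions of encoded pairwise distances, summed over
  space pairs. Where `L1` matches particles pointwise, `L3` matches the
  spaces' overall distance statistics, and is invariant to per-space
  translations and isometries of the encoded batches.

All sums are taken over batch entries as written (a `reduction = "mean"`
option divides the per-particle terms by the batch size). Both `L2` and
`L3` consume all ordered off-diagonal entries of the batch distance
matrices; using ordered rather than unordered pairs scales `L2`'s numerator
and denominator identically and leaves the stress unchanged.

## Training schedule

Mini-batches of 1,024 particles are drawn by sampling one index subset
without replacement and applying it to every landscape, so row `i` of every
batch is the same particle. Each batch is processed by the *sequential
decoder* schedule: for each decoder `n` in turn, all spaces are encoded,
decoder `n` reconstructs its space from every encoding, and one Adam update
(learning rate `1e-5` by default) is applied to decoder `n` and all
encoders — `N` optimizer updates per batch. Sequential decoder updates are
markedly more stable here than a single joint step.

The objective does not pin the three latent regularizers to a specific
decoder step, so their placement is a package choice: by default each
decoder step adds `(L1 + L2 + L3)/N`, keeping the regularizers' total
per-batch weight equal to the reconstruction term's, as in the summed
objective; `regularizer_placement = "first_step_only"` applies them once
per batch instead. Plain affine layers with biases and no
batch/layer-normalization are used throughout; weights are He-uniform
initialized from the network seed, biases start at zero, and every run is
bit-reproducible from the (network seed, training seed) pair.

## Per-particle metrics

After training, `map_to_consensus()` computes each particle's consensus
projections `Z^n = E_n(X^n)` and two error families:

* **consensus error** — the mean over space pairs of the distance between
  the particle's projections; zero when all methods place the particle at
  the same consensus state.
* **representation error** — `|| x_i^n - D_n(E_m(x_i^m)) ||` for every
  (target, source) pair, reported as a plain norm so it lives on the
  coordinate scale of space `n`.

Raw representation errors are not comparable across spaces whose
coordinates differ in scale. The package normalizes by each space's
root-mean-square pairwise distance, a dimensionless, scale-equivariant
characteristic scale estimable from the data alone: doubling a space's
coordinates (and thus its raw errors) leaves normalized errors unchanged,
and within-space rankings are preserved. This is the package's own
normalization choice for cross-space comparability.

## The consensus set

Which particles do the methods actually agree on? Particles are ranked by
ascending consensus error, and for an increasing cutoff `K` the top-`K`
projections from space 1 and space 2 are compared as two point clouds. The
comparison uses the sliced Wasserstein distance: the mean 1-D Wasserstein
distance over `kappa = 100` seeded uniform-random unit projections (the
objective leaves `kappa` free; 100 gives a stable estimate at these sample
sizes). Significance comes from a permutation test: pool the `2K` points,
randomly re-split them into two groups of `K` (100 randomizations),
recompute the distance with the *same* projection vectors — sharing
projections keeps projection noise out of the label-randomization null —
and report `p = (1 + #{d_perm >= d_obs}) / (1 + n_perm)`. The add-one
smoothing is the standard finite-permutation correction, so `p` is never
exactly zero.

As `K` grows past the well-agreeing core, the two clouds become
distinguishable and `p` drops below `alpha = 0.05`; the largest tested `K`
with `p >= alpha` defines the consensus set. The rejection direction is the
standard one-sided test (reject when the observed distance exceeds the
null); the complementary "proportion of randomized distances at or below
the observed" reading is available as `direction = "paper-text"` for
comparison, but it grows towards 1, not below 0.05, as distributions
separate, so the standard direction is the default. With more than two
spaces the per-`K` p-value is the Bonferroni-corrected minimum over all
space pairs. Ties in the agreement ranking are broken by particle id so
selections are deterministic.

## Synthetic landscapes with planted truth

Real inputs to this kind of analysis come from external heterogeneity
software, so validation uses a generator whose ground truth is known. Each
particle's true state is drawn from a 3-component Gaussian mixture in a
low-dimensional truth space — mimicking a landscape with a few discrete
states plus continuous within-state spread. Each method's view applies a
seeded affine map (orthogonal frame, random scale in [0.5, 2], offset),
optionally a mild coordinate-wise `tanh` distortion (smooth and invertible
at low amplitude), and Gaussian noise whose standard deviation is a
fraction (default 0.05) of that space's characteristic scale. Two planted
defect types carry truth labels: *discordant* particles are displaced by
1.0 characteristic scale in an independent random direction per space
(particles the methods genuinely disagree on), and *exclusive-cluster*
particles are coherently displaced in one space only (variability only one
method can see, as when a deformation-based method is blind to
compositional change).

What the generator does **not** emulate: estimation artifacts correlated
across particles, non-smooth method failures, pose-error-induced
distortions, or landscapes whose intrinsic dimensionality varies by
region. Passing the planted-truth checks therefore shows the machinery
recovers agreement structure under smooth distortions and independent
noise — not that any two real methods agree.

## Numerical choices and problem sizes

* 1-D Wasserstein distances use the exact quantile-integral form (reducing
  to the mean absolute difference of sorted samples at equal sizes); inside
  the permutation test an algebraically identical pooled-CDF form lets all
  randomizations reuse one sort per projection.
* Distance matrices are computed from Gram matrices with negative-value
  clipping and explicit symmetrization, so exact-zero diagonals and
  symmetry hold to the bit.
* Gradients of all four loss terms are hand-derived reverse-mode formulas
  over BLAS matrix ops (there is no autodiff dependency); the test suite
  verifies every path against central finite differences. The Wasserstein
  and ReLU subgradients use the standard sign/mask conventions at their
  (measure-zero) kinks.
* Degenerate cases are defined rather than left to chance: empty batches
  encode to empty matrices, duplicate input points contribute nothing to
  the stress, an all-duplicate batch raises a degenerate-batch error, and
  a final mini-batch of a single particle is skipped (distance terms need
  at least two rows).
* The packaged validation runs at desk scale: fixtures of 1,000–2,500
  particles in 2-D spaces, the published architecture width for the
  merging checks and narrower (32–64 unit) stacks for metric-level checks,
  chosen so the whole suite trains hundreds of times faster than a real
  450,000-particle analysis while exercising identical code paths. With
  only a handful of optimizer steps per epoch at these sizes, epoch counts
  are scaled up relative to a production run to reach a comparable number
  of updates; batch size is scaled down (128–256) in the training-heavy
  checks for the same reason.

## Limitations

* Particles must be matchable across landscapes (identical id sets, or
  identical row order when ids are absent); partial overlap after one
  method discarded particles is out of scope.
* The consensus space inherits whatever the inputs share. If all methods
  are wrong in the same way, agreement statistics cannot detect it.
* Relative coordinate scales of the inputs propagate into raw errors by
  design; cross-space comparisons should use the normalized errors.
* The permutation test assesses distributional indistinguishability of
  projections, not per-particle correctness; a particle can sit in the
  consensus set while being individually mis-assigned, and vice versa.
  The synthetic fixtures make this concrete: discordant particles displaced
  isotropically and scale-proportionally in *both* spaces leave the two
  projection distributions nearly identical, so a well-aligned network's
  sweep keeps them (their consensus errors still rank them last), whereas
  variability visible to only one space shifts one marginal and is caught.
  Real methods tend to fail asymmetrically — closer to the second case —
  but a selection produced by the sweep should be read as "the methods'
  state distributions agree on these particles", not as a per-particle
  correctness guarantee.
* What the p-value sweep localizes also depends on training quality: an
  under-trained network leaves systematic encoder misalignment that the
  test (correctly) detects, shrinking the consensus set. Inspecting the
  loss history for convergence before interpreting a selection is
  advisable.
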