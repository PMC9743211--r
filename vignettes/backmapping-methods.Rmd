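---
title: "Time-aware generative backmapping: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aware generative backmapping: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(backmapr)
```

## The problem

Coarse-grained (CG) molecular dynamics trades atomistic detail for
longer accessible time scales.  Recovering that detail — *backmapping*
— is ill-posed: many atomistic configurations are consistent with one
CG structure.  Frame-by-frame backmapping methods pick one of them
independently at every frame, which destroys the time correlations of
local atomic motion; quantities that depend on them (finite-difference
velocity distributions, relaxation time scales estimated from the
reconstructed trajectory) come out wrong even when every individual
frame looks fine.

`backmapr` implements a temporally coherent alternative: a conditional
variational autoencoder (cVAE) is trained on pairs of consecutive
atomistic frames so that it models the conditional distribution

\[ P(\mathrm{AA}^t \mid \mathrm{CG}^t, \mathrm{AA}^{t-1}), \]

the distribution of the current atomistic frame given the current CG
frame *and the previous atomistic frame*.  At inference the decoder is
rolled out autoregressively — each reconstruction becomes the
conditioning frame for the next step — so reintroduced detail stays
consistent from frame to frame.  This Markovian posture (one previous
frame) is the simplest time-aware conditioning and is sufficient for
the desk-scale systems shipped with the package.

## Voxelized density representation

Configurations enter the model as per-particle Gaussian densities on a
regular Cartesian lattice: `grid_spec(d, r_grid, sigma)` defines `d`
points per axis spanning `[-r_grid, r_grid]` inclusive (spacing
`2 r_grid / (d-1)`), and `voxelize()` writes, in a separate channel
per particle, the unnormalized peak-1 Gaussian
`exp(-||x_v - x_i||^2 / (2 sigma^2))` at every lattice point `x_v`.
`devoxelize()` inverts the representation by the density-weighted
average of lattice coordinates per channel.  Both maps are smooth, and
their composition recovers in-bounds coordinates to well below
10⁻³ Å once `sigma` is at least about one lattice spacing — the
aliasing error of sampling a Gaussian on a lattice decays like
`exp(-2 pi^2 sigma^2 / h^2)`, and the residual 10⁻⁴-scale error near
the enclosure margin comes from tail truncation at the grid boundary.
Amplitude normalization is irrelevant by construction because
devoxelization normalizes per channel.

Two conventions are fixed package-wide and worth stating once:
lattice endpoints are inclusive (grids are bit-reproducible from the
spec), and `sigma` may be given in Å or lattice units
(`sigma_units`), because the two readings of "a width of σ" diverge
as soon as grids are resized.  Strict voxelization demands every
particle at least `3 sigma` inside each boundary and errors otherwise;
the non-strict mode used inside training only warns, so rotation
augmentation near the margin does not abort a run.

## Model architecture

The reference architecture for voxel stacks of this kind is a 3D
residual CNN.  Interpreted R cannot train one at useful speed, so the
package uses a dense architecture that keeps every contract of the
voxel interface while exploiting its structure:

1. every density channel is collapsed to its **centroid readout** —
   exactly the weighted average that `devoxelize()` computes — and
   the readout coordinates are augmented with each frame's pairwise
   interparticle **distances**, so bond-scale geometry and the bead
   separations that signal torsional state are directly visible to
   the network rather than having to be synthesized from raw
   coordinates (coordinates scaled by `1/r_grid` to keep the `tanh`
   units away from saturation, distances likewise);
2. the decoder adds its learned per-atom displacements to a
   **bead-anchored base**: the previous-frame atoms shifted by
   linearly interpolated bead displacements, so every mapped atom
   starts exactly on its current bead, CG consistency holds by
   construction, and the network only learns the residual inner-atom
   geometry;
3. the **encoder sees only the residual** of the target relative to
   that same base (plus residual pairwise distances): everything the
   condition already determines is subtracted before encoding, which
   structurally limits the latent code to innovation-scale
   information — without this, the cheapest thing for the encoder to
   smuggle through z is the slow torsional state, and sampling the
   marginal latent prior at rollout then randomizes that state
   against the CG condition;
4. a stack of fully connected residual blocks (`hidden` units,
   `n_blocks` blocks) maps features to a diagonal-Gaussian posterior
   of dimension `d_latent` (encoder) or to the displacements
   (decoder);
5. the displaced atoms are re-rendered as Gaussians on the lattice
   ("Gaussian splatting"), producing the reconstructed density grid,
   and the coordinate output is exactly `devoxelize()` of that grid.

Everything from input voxels to every loss term is a composition of
smooth functions; the gradients are hand-derived and verified against
central finite differences to 10⁻⁴ relative error in the test suite.
Because the readout discards the spatial profile beyond the centroid,
this architecture cannot represent multi-modal single-channel
densities the way a CNN decoder could; for the point-particle systems
targeted here the channel density *is* a single Gaussian and nothing
is lost.  `d_latent` defaults to 16 — the readout features live in a
`3(2N+n)`-dimensional space, so latent spaces sized for CNN feature
maps (64+) would be pure overhead.

## Training objective

For one sample the loss is

```
total = voxel_mse + coord_mse + cg_mse + edm_mse
        + lambda * w_E * energy_mse + beta * kl
```

with all reconstruction terms means over all their entries, the
energy term a squared difference of scalar potential energies, and
`kl` the closed-form divergence of the diagonal posterior from
N(0, I).  `lambda` follows an exponential warm-up
(`lambda_schedule`): zero for `warmup` steps — the potential energy is
brutally sensitive to misplaced atoms early in training — then
`1 - exp(-rate (step - warmup))`.  `beta` is either constant 1 or the
cyclic ramp-and-hold schedule (`beta_schedule`) used to counter KL
vanishing.

Three scale facts about this objective at desk scale drove the default
settings, all exposed in `train_control()`:

* reconstruction MSEs are O(10⁻²) Ų while the KL is O(1–10) nats;
  at `beta_max = 1` the optimizer buys KL reduction with posterior
  collapse and the latent code goes unused.  Conversely at very small
  `beta` the encoder leaks the *answer* through z — including the
  discrete torsional state — and marginal-prior sampling at rollout
  then randomizes that state.  `beta_max` is therefore a genuine
  model-selection knob; the package default keeps the KL at a few
  nats so z carries thermal detail but not information the CG
  condition already determines.
* the energy term is O(10–100) kJ²/mol² against O(10⁻²) partners;
  `weights = list(energy_mse = ...)` rescales it to be commensurate
  (the schedule's `lambda` continues to gate when it acts at all).
* per-sample mean-centering uses the CG-frame centroid for all three
  frames of a triplet, preserving their relative displacements — the
  signal temporal conditioning relies on.  One shared random rotation
  per sample (uniform on SO(3) via random unit quaternions — uniform
  Euler angles are *not* uniform on the group) teaches rotational
  covariance.

Three augmentations address the gap between teacher-forced training
and autoregressive inference (exposure bias), which manifested during
development as unbounded drift of the non-bead atoms within ~100
rollout frames:

* **condition noising** (`condition_noise`, Å): Gaussian noise on the
  previous-frame condition teaches the decoder to contract condition
  errors of the magnitude its own rollout produces;
* **condition dropout** (`condition_shuffle`): with small
  probability the previous frame is replaced by a random frame of the
  same trajectory, so the decoder learns to rebuild inner-atom
  geometry from the CG frame alone — the situation at rollout seeding
  and right after rare torsional transitions;
* **scheduled sampling** (`rollout_fraction`, `rollout_depth`): with
  a probability that ramps up over the first half of training, the
  previous-frame condition is produced by rolling the current model
  itself autoregressively for a random number of steps from an
  earlier true frame (no gradient through those steps).  One-step
  condition corruption cannot expose the slow geometric collapse
  that only develops over tens of self-fed steps; multi-step
  self-rollouts do, and the loss then explicitly trains the decoder
  to pull its own compounded errors back onto the data manifold.

A related design point: a *deterministic* decoder (large `beta_max`,
latent unused) is not a safe fallback.  Iterating a conditional-mean
map relaxes toward the mean configuration, whose bond lengths are
contracted by angular averaging — measured on the tetramer, the
iterated fixed point collapses the outer bonds from 1.5 Å toward
~1.1 Å.  Per-step stochasticity through the latent code is what keeps
the rollout on the data manifold, which is why the KL weight is a
genuine model-selection knob rather than a nuisance parameter.

## Inference

After training the encoder is evaluated once over the training set and
a 10-component Gaussian mixture (`fit_latent_prior`, via `mclust`) is
fitted to the posterior means — ex-post density estimation.  Sampling
this mixture instead of the assumed N(0, I) prior keeps the decoder in
latent regions it actually visited during training.  The mixture is
fitted to posterior means rather than sampled codes: the means are the
deterministic summary of the aggregated posterior, and adding the
per-sample posterior noise back in would double-count variance the
decoder already receives through z at training time.

`backmap_trajectory()` seeds the rollout with a training-set frame:
the frame whose CG projection best matches the first CG frame to
backmap (aligned RMSD on beads, Kabsch), taking its *predecessor* as
the "previous atomistic frame" and rigidly aligning it (rotation from
the beads, applied to all atoms; when the best match is the first
frame, that frame itself is used).  Each rollout step re-centers on
the current CG centroid exactly as in training; whether to re-center
per step was genuinely open, and consistency with the training-time
transform was the deciding argument.

## The toy systems and what they do (not) show

`make_benchmark_system()` ships two bead-spring systems integrated by
a BAOAB-splitting underdamped Langevin integrator (Rcpp; all noise
through R's RNG, so runs are bit-reproducible under a seed):

* **dimer** — two atoms, one harmonic bond (k_b = 100 kJ/mol/Ų,
  r₀ = 1.5 Å), CG = first atom.  Its bond-length variance has the
  closed form kT/k_b, used as an equipartition check.
* **tetramer-2state** — a four-atom chain (three bonds as above, two
  harmonic angles k_a = 40 kJ/mol/rad², θ₀ = 109.5°) with one
  torsional double well `0.5 * barrier * (1 - cos 2 phi)`; the
  default barrier of 6 kJ/mol is ≈ 2.4 kT at the default
  kT = 2.479 kJ/mol (300 K), giving two metastable torsional states
  with dwell times of a few hundred recorded frames — long against
  the frame spacing, short enough to sample tens of transitions in a
  desk-scale run.  CG = the two end atoms, the minimal analogue of a
  small peptide's metastable backbone-dihedral structure.

Integration uses dt = 2 fs (the stiffest bond's period is ~0.2 ps),
friction 2 ps⁻¹, masses of 12 amu, and a recording stride of 10 steps
(frame spacing 0.02 ps), chosen so consecutive recorded frames are
strongly correlated but visibly distinct.  These physical settings
define the study conditions for every quantitative check in the test
suite and were fixed before any end-to-end evaluation.

What the toy trajectories emulate: sequential correlation, rotational
and translational diffusion, equipartition-consistent bonded
fluctuations, and rare two-state torsional kinetics — the features the
temporal conditioning and the evaluation battery exercise.  What they
do not emulate: solvent and nonbonded-dominated energetics, many-body
steric frustration, hydrogens, multi-chain topologies, or the
hundreds-of-atoms scale of real proteins.  Passing tests on these
systems validate the machinery (representations, losses, gradients,
rollout, estimators), not chemical transferability.

## Evaluation battery

`evaluate_backmapping()` and the underlying functions mirror the
standard structural / thermodynamic / kinetic comparisons:

* potential-energy distribution overlap plus a two-sample KS summary
  (the visual-comparison stand-in);
* free-energy surfaces `-ln` of (optionally reweighted) histograms,
  min-shifted, empty bins `NA`; Markov-model stationary reweighting
  assigns frame weights `pi_i / N_i`;
* torsion angles by the two-plane-normal atan2 construction; pairwise
  distance features in fixed lexicographic order (45 for 10 beads);
* TICA by the symmetrized time-lagged covariance generalized
  eigenproblem (eigenvalues bounded in [-1, 1]; the constant
  component removed by mean-centering; degenerate feature columns
  rejected by name);
* Markov state models: k-means centroids fitted once on reference
  data and *frozen* for assigning any other trajectory; reversible
  maximum-likelihood transition matrix by the standard fixed-point
  iteration on the largest connected set; implied timescales
  `-tau / ln lambda_i`; slowest-process normalization for the uniform
  acceleration of CG dynamics; eigenvector cosine similarity on
  mutually occupied states with absolute value (eigenvector signs are
  arbitrary);
* finite-forward-difference velocity distributions, with the
  constant-factor rescaling that matches distribution means.

The MSM lag for the tetramer analyses defaults to 25 frames (0.5 ps):
short enough to resolve the slow torsional process, long enough that
the two-state discretization is approximately Markovian.  TICA lags
default to the same order.  Both are configuration, not physics.

## Numerical choices and degenerate inputs

* Kabsch alignment uses SVD with a determinant sign correction
  (reflections excluded); under three points or collinear geometry it
  warns and returns a best-effort result — with a two-bead CG the
  rotation about the bead axis is a gauge freedom, and downstream
  code treats it as such.
* `devoxelize()` raises a degenerate-density error on any zero-mass
  channel rather than silently returning the grid center.
* The reversible MSM fixed point is iterated to 10⁻¹² with
  symmetrized-count initialization; eigenvalues come from the
  `sqrt(pi)`-similarity-transformed symmetric matrix, so they are real
  by construction.
* k-means ties and restarts are controlled by an explicit seed;
  assignment of new data uses squared-distance argmin with first-index
  tie-breaking.
* The Langevin integrator aborts with the offending step index when a
  coordinate exceeds a guard bound — a stability error, not a warning.

## Problem sizes used by the shipped checks

The end-to-end recovery check trains on a single tetramer trajectory
of 6,000 recorded frames (60,000 integration steps, 120 ps), for
9,000 optimizer steps at batch size 16, then backmaps a held-out
trajectory of several hundred frames; estimator checks use chains of 10⁶ steps and
toy simulations of (2–6)·10⁵ steps.  These sizes give sampling errors
comfortably inside the stated tolerances for every closed-form
comparison while keeping a full run on one laptop core in the minutes
range.

## Known limitations

* The dense readout architecture is blind to sub-voxel density shape;
  systems whose channels are genuinely multi-modal need the CNN
  variant this package deliberately does not implement.
* The same architecture limits how sharply the *conditional
  covariance* of atomic displacements can be shaped: per-step
  sampling noise in bond directions exceeds the true one-frame
  innovation, so autoregressively backmapped trajectories reproduce
  CG consistency and velocity scales well but over-disperse and
  slightly contract hard internal coordinates (bond lengths) relative
  to the reference ensemble.  The end-to-end checks quantify this
  (the bond-length Wasserstein comparison in the test suite and
  acceptance script); convolutional or equivariant decoders are the
  known remedy and are out of scope here.
* One previous frame of memory cannot represent inertial effects
  beyond what positions encode; velocity-aware conditioning is out of
  scope.
* The ex-post mixture prior samples the *marginal* latent
  distribution; condition-dependent latent structure that the decoder
  has not disentangled from the condition shows up as excess
  conformational noise in rollouts.  The `beta_max` discussion above
  is the practical mitigation.
* Periodic boundary conditions, shared multi-particle channels and
  force-based CG force-field fitting are explicitly out of scope.
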