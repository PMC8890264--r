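---
title: "Methods: grid-based molecule generation in gridmol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based molecule generation in gridmol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gridmol implements a complete toolchain for structure-based molecular
generation with atomic density grids: property-based atom typing, grid
rendering, a receptor-conditional variational autoencoder (CVAE) over
grids, density-to-structure inversion by atom fitting, rule-based bond
inference, sampling controls, and molecule-level evaluation metrics. This
vignette is the package's account of the underlying model, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Atom typing

Every heavy atom is mapped to an 18-channel type vector: an 11-value
one-hot element block (ligand role: B, C, N, O, F, P, S, Cl, Br, I, Fe;
receptor role: C, N, O, Na, Mg, P, S, Cl, K, Ca, Zn), a 2-value
aromaticity block, single-channel H-bond acceptor and donor indicators,
and a 3-value formal charge block (-1, 0, +1). Properties are
concatenated in that fixed order; within a property, values follow the
listed order. Receptor and ligand atoms use two separate 18-channel
schemes rather than one shared 29-channel vector, because the steric
clash functional multiplies a receptor grid with a ligand grid and the
two must live on separate channel sets anyway. Hydrogens are never typed
or gridded; they are recovered downstream by bond inference from valence
arithmetic.

Aromaticity, H-bond roles and formal charges are perceived from the
input structure's bonds and annotations by a deliberately simple,
documented pass (`perceive_properties()`): a ring of five or six C/N/O/S
atoms is aromatic when atoms carrying a double bond (one pi electron
each) plus lone-pair heteroatoms (two each) reach a count of six; donors
are N/O with at least one hydrogen; acceptors are N/O with nonpositive
formal charge, excluding pyrrole-type N-H. These rules cover the small
drug-like chemistry of the fixture set; they are not a full aromaticity
model (quinoid systems, for example, are out of scope).

## Density grids

Molecules are rendered on cubic grids with side 23.5 Å and 0.5 Å
resolution, lattice points on both boundary faces, hence 48 points per
axis. The density kernel is a truncated Gaussian

$$f(d, r) = \exp(-2 d^2 / r^2), \quad d \le 1.5\,r, \qquad 0 \text{ beyond},$$

with the atomic radius fixed at $r = 1$ Å for all atoms. The kernel form
and cutoff multiplier are configurable (`grid_spec()`), and the voxel
value of channel $c$ is $\sum_a t_{ac}\, f(\lVert x_a - p \rVert, r)$ —
every atom whose kernel support intersects the grid contributes, with no
atom-count cap. Grids are centered on the input ligand's heavy-atom
centroid; pose augmentation applies a uniform random rotation (quaternion
method) plus a per-axis uniform translation to the complex about the grid
center. The translation amplitude is not pinned by the training protocol
we follow; we default to ±2 Å per axis, a customary scale for 0.5 Å
grids.

The gridder exposes analytic partial derivatives of the L2 objective
with respect to atom coordinates (`grid_l2_gradient()`), validated
against central finite differences at 1e-5 tolerance in the test suite;
atom fitting depends on them.

The steric clash functional sums each grid across channels and
integrates the product of the two channel sums over the grid. Fixture
complexes are built with a ligand-receptor gap larger than twice the
kernel support radius (3 Å), so their overlap is exactly zero — the
property that makes the functional usable as a clash loss; the
shrunken-cavity fixture is the negative control.

## Atom fitting

Inverting a density grid back to atoms is solved by iterative detection
plus joint gradient descent. Detection takes 26-neighbor local maxima of
the residual (reference minus current model) restricted to the element
channels, at or above `peak_threshold` (default 0.25, half the smallest
meaningful one-hot contribution at one voxel diagonal); property
channels never seed atoms — they only decorate an element peak (set at
residual ≥ 0.5), which resolves the representational ambiguity of one
atom activating several channels. Refinement runs plain gradient descent
on all coordinates jointly with backtracking step halving and growth
(initial step 0.1 Å), keeping the best iterate; the per-trial loss is
tracked incrementally through the voxel updates, and the exact loss is
recomputed at the end of each refinement to clear accumulated drift.
Rounds are accepted while the L2 improves by more than
`convergence_tol` (1e-4) of the previous loss; fitting also stops at
`max_atoms` (80) or an empty candidate list. `beam_width` > 1 expands
each kept structure with its top candidates and retains the best few;
the default is greedy (width 1), which the exhaustive-enumeration oracle
on single-channel 8³ grids shows to be sufficient at these densities.

At the study conditions (200 seeded fixtures, 5–20 atoms, ≥ 2 Å
separation, default grid), the suite requires ≥ 99 % exact recovery of
atom counts and type vectors, mean coordinate error < 0.05 Å, and final
L2 < 1e-2 per molecule.

## Bond inference

Bond inference is a fixed, deterministic rule order: distance-based
connection (bond proposed when the distance is within the Cordero
covalent radii sum plus 0.45 Å, above a 0.4 Å clash floor), pruning of
over-valent atoms longest-bond-first, aromatic ring perception over
5-/6-rings of aromatic-typed atoms, kekulization, geometric bond-order
raising, formal charges read from the type vectors (never re-perceived
from geometry — the charge channels are the model's output contract),
implicit hydrogen filling, and a sanity pass (single fragment, valences
within bounds).

Kekulization is a matching over the aromatic bonds that must cover every
aromatic carbon; donor-typed heteroatoms (pyrrole-type N-H) are excluded
from matching, so they keep two single ring bonds and one hydrogen,
while pyridine-type nitrogens get matched through the ring's parity.
Failure to find a cover marks the molecule invalid with reason
`kekulization/aromaticity failure`. Hydrogen counts fill the element's
default valence (e.g. P fills to 3, S to 2) while validity is judged
against the maximum valence (P 5, S 6), both adjusted by formal charge.
Order raising walks non-aromatic bonds shortest-first and raises an
order when the bond length is below the midpoint between the typical
lengths of adjacent orders and both atoms have free valence; one valence
unit is reserved on donor-typed atoms so they can keep their hydrogen.

The full round trip — type, grid, fit, bond — must reproduce the input
canonical SMILES for ≥ 90 % of the 40-molecule curated list shipped
under `inst/extdata/` (3D conformers with explicit hydrogens; canonical
SMILES via OpenBabel). The list was curated to span the ligand element
palette and the common functional groups whose bond orders are
geometrically well-posed (alkanes, alcohols, amines, carbonyls, acids,
amides, nitriles, alkynes, aromatics including fused and five-membered
heteroaromatics, organohalogens, a phosphate and a sulfone).

## The conditional VAE

The generative model is a CVAE over grids. The input encoder consumes
the channel-concatenated receptor and ligand grids and outputs the mean
and log-standard-deviation of a diagonal Gaussian posterior (the std is
exponentiated, hence strictly positive). The conditional encoder maps
the receptor grid to a conditional vector and per-level skip feature
maps; the decoder concatenates the latent and conditional vectors, maps
them through a dense layer to the bottom-resolution feature map, and
upsamples (nearest neighbor) with U-Net-style channel concatenation of
the conditional encoder's skip features, ending in a softplus so every
output voxel is nonnegative. Convolution blocks are kernel-3 3D
convolutions with leaky-ReLU activations and identity residuals where
channel counts match, alternated with 2× average pooling. Spectral
normalization (power-iteration estimate of the leading singular value;
u, v advanced once per optimizer step and treated as constants in the
gradient) is applied to all weight matrices and can be toggled off.

Because no neural-network framework is available to the package, the
convolutions, backward passes and RMSprop optimizer are implemented in
the package itself (C++ im2col + BLAS for the convolutions). The entire
loss gradient is checked against central finite differences at 1e-3
relative tolerance in the test suite, with spectral normalization
active.

The training loss is the weighted sum
$L = \lambda_{recon} L_{recon} + \lambda_{KL} L_{KL} + \lambda_{steric} L_{steric}$
with $\lambda_{recon} = 4.0$, $\lambda_{steric} = 1.0$, and
$\lambda_{KL}$ ramped linearly from 0.1 to 1.6 over 200 000 iterations
starting at iteration 450 000 (constant outside the ramp). The
reconstruction term is summed squared voxel error (a Gaussian likelihood
up to constants; a mean form is available by configuration), the KL term
is the diagonal-Gaussian closed form, and the steric term applies the
clash functional to the receptor and the generated ligand grid. Training
uses RMSprop (default learning rate 1e-5, batch size 8) with fresh pose
augmentation each iteration and reparameterized latent samples
$z = \mu + \sigma \varepsilon$.

Architecture sizes that the reference description leaves open — latent
dimension, level count, filter widths — default to 128 / 3 levels /
widths doubling from 32, all configurable. The desk-scale test profile
uses 12³ grids, two levels with widths (8, 16), latent dimension 16,
batch size 2 and learning rate 1e-4 (the reduced model tolerates a
larger step), trained for 2000 iterations on five fixture complexes;
trainability is asserted as a ≥ 90 % reduction of the reconstruction
loss from its initial value. This is a proxy for trainability only: the
full-scale run (10⁶ iterations on a docked-complex corpus) is far
outside one-CPU scope, so nothing here validates generation quality on
real receptors.

## Sampling controls

The variability factor scales the latent standard deviation,
$z' = \mu + \lambda_{var}\,\sigma\,\varepsilon$ with standard-normal
reparameterization noise $\varepsilon$ (at $\lambda_{var} = 0$ every
sample equals the mean). The bias factor linearly interpolates the
sampled distribution's parameters between prior
($\lambda_{bias} = 0$: $\mu = 0, \sigma = 1$) and posterior
($\lambda_{bias} = 1$). Latent interpolation between encoded ligands is
spherical: the direction rotates at constant angular speed in the plane
of the endpoints while the norm interpolates linearly — a choice made
here because latent Gaussians concentrate near a shell, making arc
interpolation better behaved than chords; antiparallel endpoints fall
back to linear interpolation with a warning. Each sample index derives
its own RNG stream from the master seed, so sample k is reproducible
regardless of how many samples are drawn.

## Evaluation metrics

A molecule is valid iff it is a single connected fragment and passes an
independent sanitization (valence bounds plus a kekulized round trip
through OpenBabel's canonical SMILES writer). Novelty and uniqueness are
membership tests of the canonical SMILES against the training set and
the already-generated set; since both require a canonical SMILES, the
default denominators are valid molecules, and aggregates over all
samples are reported alongside. Tanimoto similarity is the bit-set
intersection over union of OpenBabel FP2 fingerprints (1024-bit path
fingerprint — the configurable default here, as no 2048-bit path
fingerprint is exposed by the toolkit the package builds on), and
per-target diversity is the reciprocal mean similarity over unordered
distinct pairs. UFF relaxation (obminimize) reports the energy change
and the heavy-atom RMSD between pre- and post-minimization poses under
identity atom mapping, without symmetry correction (the poses share atom
indices); the customary "< 2 Å" gate is a downstream threshold on that
RMSD. The receptor context is not part of the minimization — only
internal strain is relaxed — which overstates mobility slightly for
tightly packed pockets.

Latent interpolation between several ligands of one receptor
(`latent_interpolation()`) encodes each ligand to its posterior mean,
runs the spherical trajectory through those vectors, and decodes each
step; the conditional grid center moves along the linear interpolation
of the segment endpoints' ligand centroids, so the decoded densities
track the binding site smoothly.

## External scoring interface

Docking-score and learned-affinity evaluation of generated molecules is
delegated to external tools through a simple subprocess contract rather
than bundled: the scorer is any executable invoked as
`scorer <receptor.pdb> <ligands.sdf>` that writes one JSON object per
ligand (fields `score`, and optionally `minimized_sdf`) to standard
output. `write_sdf()` and `read_structures()` produce and consume the
files on each side. No scorer ships with the package.

## Run configuration

`read_run_config()` / `write_run_config()` serialize the four
configuration objects (architecture, training, loss weights, fitting)
as one YAML file with sections `model`, `train`, `weights`, `fit`;
unknown keys are rejected rather than silently ignored.

## Synthetic fixtures: what they do and do not show

Random fixture molecules place typed atoms at ≥ 2 Å separation in a
12 Å box with random H-bond roles and occasional ±1 charges on N/O; they
exercise the grid representation and its inversion, not chemistry. The
curated list exercises bond inference on realistic geometry. Fixture
complexes (a receptor shell around a cavity holding the ligand)
guarantee zero steric overlap by construction. None of these reproduce
docked-pose noise, conformational strain, receptor flexibility, or the
chemical diversity of a real corpus — passing tests demonstrate the
correctness of the representation, the inversion, the optimization and
the metrics, not generative performance on real targets.

## Numerical choices and limitations

* Peak detection ties: candidates are ordered by residual value then
  lexicographic voxel index; plateau duplicates resolve in later rounds
  as the residual shrinks.
* Refinement terminates on a gradient-infinity-norm floor (`gd_tol`,
  default 1e-7), a collapsed step size, or the iteration budget;
  accepted rounds never increase the L2.
* The truncated kernel is discontinuous at its support boundary (it
  drops from exp(-4.5) ≈ 0.011 to 0), so the L2 surface jumps wherever
  a voxel crosses an atom's cutoff sphere and gradient descent can
  stall a hair away from an exactly-on-lattice optimum. Fitting
  therefore ends with a lattice-snap polish: each atom is tentatively
  rounded to its nearest grid node and the move is kept only if the L2
  strictly improves. Off-lattice optima reject the snap, so the polish
  is inert on realistic inputs.
* The incremental L2 bookkeeping is exact up to floating-point
  accumulation; the final loss of each refinement is recomputed from a
  fresh residual.
* Grid serialization is NPY v1.0 (Fortran order, float64) plus a JSON
  geometry sidecar; round trips are bit-exact. A minimal NPY
  reader/writer is included because no installed package provides one.
* Stereochemistry, protonation-state enumeration and tautomer
  canonicalization are out of scope for bond inference; molecules whose
  identity depends on them will count as round-trip failures.
* The study sizes used by the suite and acceptance script (200 and 100
  recovery fixtures, 50 oracle grids, 1500-2000 training iterations)
  were chosen as the smallest sizes at which the assertions are stable
  under reseeding.
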