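---
title: "Surface shape descriptors for protein fold search: models and methods"
author: "zdsurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface shape descriptors for protein fold search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdsurf)
```

## The problem

Structure-prediction pipelines now produce millions of protein models, and
the practical question "which known structures look like this one?" has to
be answerable in seconds, not the minutes-per-pair of structural alignment.
`zdsurf` addresses this with a global shape signature: the molecular
surface is voxelized and expanded in an orthonormal polynomial basis on the
unit ball, and the rotation-invariant norms of the expansion coefficients
form a compact vector that can be compared by simple distance or fed to a
trained pair classifier. Around that core the package provides the
supporting machinery such a search service needs: structure ingestion,
confident-domain extraction from per-residue pLDDT confidence profiles,
coarse secondary-structure class assignment, and a ranked descriptor index
with a command-line surface.

## The shape descriptor

### Surface generation

The solvent-excluded surface is approximated as the iso-surface, at the
probe radius $r_p$ (default 1.4 Å, a water-sized probe), of the Euclidean
distance field of the union of atom van der Waals spheres,

$$d(\mathbf{x}) = \min_i\left(\lVert \mathbf{x} - \mathbf{c}_i \rVert - r_i\right),$$

sampled on a regular grid (default 0.7 Å) and triangulated by marching
tetrahedra. Each grid cube is split into six tetrahedra fanned around its
main diagonal; the face diagonals this induces are consistent between
neighbouring cubes, so the extracted mesh is closed — a single atom yields
a topological sphere (Euler characteristic 2), which the tests verify.
Van der Waals radii are fixed in-code (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, default 1.70 Å, Bondi-style). Two atom subsets are supported:
`full_atom` (all heavy atoms) and `main_chain` (backbone Cα, C, N only),
the latter producing a smoother surface that in the original retrieval
literature performed better for fold recognition.

This offset-surface construction is a single-pass approximation: it
inflates the van der Waals union by the probe radius rather than rolling a
probe and re-entering crevices, so deep re-entrant geometry is slightly
smoothed relative to a true rolling-probe surface. At the coarse grids the
descriptor consumes, this distinction is below the discretization noise
floor.

### Voxelization

The mesh is mapped onto an $N^3$ cubic grid ($N = 200$ in production;
tests and examples use $N = 64$). A voxel is set to 1 exactly when the
distance from its center to the nearest mesh triangle is smaller than 1.7
grid intervals, and 0 otherwise, giving a binary shell function
$f(\mathbf{x})$. Distances are exact point-to-triangle distances; each
triangle only visits the voxels inside its bounding box expanded by the
cutoff, which provably covers every voxel it can mark (the equivalence
with the exhaustive all-voxels scan is tested bit-for-bit on small grids).

One design choice here deserves emphasis. The obvious grid scaling — fit
the mesh bounding box tightly into the cube — makes the grid spacing, and
with it the *physical thickness* of the 1.7-interval shell, depend on the
molecule's orientation (an elongated object's bounding box varies by up to
$\sqrt{3}$ between orientations). That injected a global orientation
artifact of tens of percent into every descriptor component. `zdsurf`
instead derives the spacing from an exactly rotation-invariant size
reference computed from the atoms,
$R = \max_i(\lVert\mathbf{c}_i - \bar{\mathbf{c}}\rVert + r_i) + r_p$,
carried on the mesh, and centers the grid on the atom centroid. The
bounding box still fits with the required margin (at least cutoff + 1
voxels per side), and the voxel pattern now translates and rotates with
the molecule up to pure lattice discretization.

### Zernike expansion

The occupancy function is mapped into the unit ball — occupied voxel
centers are centered on their centroid and scaled to a maximum radius of
0.6, keeping the shape strictly inside the ball where the basis is
orthonormal — and projected onto the Zernike–Canterakis basis

$$Z_{nl}^m(r, \vartheta, \varphi) = R_{nl}(r)\, Y_l^m(\vartheta, \varphi),
\qquad 0 \le l \le n,\; (n - l)\ \text{even},\; -l \le m \le l,$$

where $Y_l^m$ are spherical harmonics (computed by stable normalized
associated-Legendre recursions with the Condon–Shortley phase) and
$R_{nl}$ are the Canterakis radial polynomials, normalized so that the
basis is orthonormal under the inner product
$\langle f, g\rangle = \tfrac{3}{4\pi}\int_{|\mathbf{x}|\le 1} f\,\bar g\,
\mathrm{d}\mathbf{x}$ (verified numerically by dense quadrature in the
tests). The moments

$$\Omega_{nl}^m = \frac{3}{4\pi} \int_{|\mathbf{x}| \le 1}
f(\mathbf{x})\, \bar{Z}_{nl}^m(\mathbf{x})\, \mathrm{d}\mathbf{x}$$

are evaluated by direct summation of $\bar Z$ over occupied voxel centers
times the voxel volume, grouped per degree $l$ into one matrix product, and
completed for negative $m$ by the conjugation symmetry
$\Omega_{nl}^{-m} = (-1)^m\,\overline{\Omega_{nl}^{m}}$ that holds for any
real field (asserted to $10^{-10}$ in the tests, and a free correctness
check on the harmonic conventions). The rotation-invariant descriptor
collapses each $(2l+1)$-block into its norm,

$$F_{nl} = \sqrt{\sum_{m=-l}^{l} \left|\Omega_{nl}^m\right|^2},$$

using the squared modulus: the literal complex square that a compact
notation might suggest is neither real nor rotation invariant, and the
modulus form is the one used throughout the moment-invariant literature.
At the default order $n_{\max} = 20$ there are exactly 121 valid $(n, l)$
pairs, so a structure becomes a 121-component non-negative vector.

Two details are deliberate deviations from the most literal reading of the
normalization convention, both made because implementation measurements
showed the literal rule breaking rotation invariance at test grid sizes:

* **Scale reference.** Scaling so that the farthest *occupied voxel
  center* sits exactly at radius 0.6 lets a sub-voxel wobble of that
  single extreme voxel rescale the whole object between orientations;
  high-order radial polynomials amplify such scale jitter strongly. Grids
  produced by `voxelize_surface()` therefore carry the rotation-invariant
  outer shell radius derived from the mesh size reference, and
  `normalize_grid()` uses it as the scale denominator (never smaller than
  the observed radius, so every point stays inside the ball). For plain
  grids built with `as_voxel_grid()` — synthetic shells, hand-made
  patterns — the exact max-radius rule applies unchanged.
* **Measured effect.** With both stabilizations, five random rotations of
  each test fixture at $N = 64$ agree with the unrotated descriptor to
  within 2% of the dominant-component scale with cosine similarity above
  0.999; with the literal rules the deviation was 3–30%. At $N = 200$ the
  discretization noise shrinks roughly with the grid ratio.

What remains orientation-dependent is pure voxel-lattice discretization:
which voxels fall inside the 1.7-interval shell. This is the accuracy
floor of a binary shell at a given $N$, and the reason per-component
agreement is stated relative to the dominant scale rather than each tiny
component's own magnitude.

## Pair scoring

Two scoring routes are provided.

**Direct descriptor score.** $s = 1/(1 + \lVert F_a - F_b \rVert_2)$,
in $(0, 1]$, with a default same-fold decision threshold of 0.1.

**Siamese network.** A shared three-layer ReLU encoder (widths 250, 200,
150) maps each descriptor to a 600-component encoding (the concatenation
of all three hidden layers). The comparator input concatenates both raw
descriptors, both encodings, four comparison metrics — Euclidean distance,
cosine distance, Manhattan (summed absolute) distance, and dot product —
applied to the raw descriptors and again to the encodings, and the signed
differences in surface-mesh vertex and face counts:
$2\cdot 121 + 2\cdot 600 + 2\cdot 4 + 2 = 1452$ features. Reducing the
element-wise metrics to scalars is the only reading consistent with that
count. One ReLU hidden layer (128 units, configurable) and a sigmoid
output give the probability that the two structures share a fold. Default
decision thresholds are 0.5 for full-atom descriptors and 0.6 for
main-chain descriptors; the direct score uses 0.1.

Training minimizes binary cross-entropy with ADAM (learning rate 0.005)
over balanced mini-batches of 32 positive and 32 negative pairs; gradients
are derived by hand through every path, including the metric scalars
(Euclidean, cosine, Manhattan and dot-product derivatives with
zero-norm guards), and are verified against central finite differences in
the test suite. Training is deterministic given its seed; when a
validation fraction is set, the best-validation-loss parameters are kept.
The raw network is not exactly symmetric in its two arguments, so
`nn_score()` reports the mean of both orderings — a pair relation should
not depend on argument order. The stopping rule is a fixed epoch count
(default 30): at the desk-scale problem sizes used here the loss plateaus
well before that, and a fixed count keeps runs bit-reproducible.

Two points where the architecture is underdetermined and the package makes
its own call: the hidden activations are rectified linear (the
conventional default, recorded in the config), and the comparator has one
hidden layer of 128 units — the smallest head that trained stably on the
synthetic benchmark; both are configurable.

## Confident domains from pLDDT profiles

Predicted models carry a per-residue confidence (pLDDT, 0–100, stored in
the B-factor column; profiles whose maximum is ≤ 1 are assumed to be on a
0–1 scale and rescaled ×100 on ingest). A confident domain is extracted
as:

1. every maximal run of residues with pLDDT strictly greater than 70.0
   whose length is strictly greater than 50 (so 51+ residues qualify;
   exactly 50 do not);
2. runs separated by at most 5 residues are merged, the interveners
   included regardless of their confidence, transitively until a fixpoint
   (a chain of runs each separated by small gaps collapses into one
   region);
3. post-merge lengths are not re-filtered — each constituent run already
   passed the length test.

The gap counts *all* residues between two qualifying runs, including short
confident stretches that were themselves too short to qualify. Both
boundary readings (strict > 50, inclusive ≤ 5) are pinned by tests, and
the whole rule is checked against an independently written quadratic-scan
oracle on ten thousand seeded random profiles. The profile generator
refuses a run level of exactly 70.0 so no fixture can sit on the ambiguous
boundary.

## Secondary-structure classes and folds

Coarse classes (α, β, αβ, small) are assigned three ways:

* **Expert cascades** (first match wins): the *original* rule — length
  < 50 aa → small; helix ≥ 60% → α; sheet ≥ 35% and helix < 20% → β;
  otherwise αβ — and the *optimized* rule with thresholds 55 aa, 55%, 25%
  (same 20% helix guard). A 5%-step grid sweep verifies the cascades are
  total and match a direct vectorized restatement branch for branch.
* **Bagged SVM**: twenty radial-basis-kernel SVMs, each trained on a
  bootstrap sample (with replacement) of 5% of the data, predicting by
  majority vote; ties break by summed class probabilities, then
  lexicographic class order. Features (length, helix fraction, sheet
  fraction) are standardized with training statistics — an addition for
  kernel stability, recorded in the model object. Samples with fewer than
  two classes are redrawn (at most 100 attempts). Default RBF
  hyperparameters: γ = 1/3 (one over the feature count), cost 1.
* **Geometric content assigner**: helix/sheet fractions from Cα geometry —
  a residue is helical when its i→i+3 and i→i+4 Cα distances fall in
  windows around 5.1 and 6.2 Å *and* the window condition holds at two
  consecutive positions (a lone hit, e.g. where the chain folds back
  between strands, is not a helical turn); strand when its i→i+2 distance
  is extended (6.2–7.2 Å) and another extended residue lies within 5.5 Å.
  Any standard assigner can be substituted by passing precomputed
  fractions; the geometric one keeps the package free of external
  dependencies and is validated on ideal helix/sheet/coil fixtures.

Fold assignment compares a query descriptor against up to 10 exemplars
sampled (seeded, without replacement) from each catalogue fold and
returns the fold with the highest pair score. The per-fold aggregate is
the *maximum* over exemplar scores — "the fold that showed the highest
probability" reads as a max over comparisons — with mean aggregation
exposed as an option. Ties break lexicographically by fold id.

Evaluation metrics are the standard confusion-matrix quantities: accuracy
$(TP+TN)/(TP+TN+FP+FN)$, precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, and
F-measure $2PR/(P+R)$; a metric whose denominator is zero raises an error
naming it rather than returning NaN.

## Search

`build_index()` computes one descriptor per structure file (per-file
failures are collected into a report, not fatal unless everything fails)
and `search_index()` scores every entry against a query by either method,
sorting by score with ties broken by id. The displayed distance is
$1 - \text{score}$, so a same-fold-certain network hit displays 0.0. The
on-disk index is a single JSON archive (manifest plus full-precision
descriptor matrix): portable, versioned, diff-able. The ranking is tested
equal to a brute-force sort, invariant under entry-order permutation, and
stable through a disk round-trip.

## The synthetic-data generators

Nothing in the package requires a structure database; every statistical
claim is exercised on generators with known ground truth, each a pure
function of its seed:

* `make_ideal_helix()` — poly-alanine backbone on an ideal α-helix (rise
  1.5 Å, 100°/residue, Cα radius 2.3 Å, consecutive Cα–Cα 3.8 Å); N, CA,
  C, O at idealized cylindrical offsets. With zero jitter the output is
  bit-identical regardless of seed.
* `make_ideal_sheet()` — antiparallel extended strands (i→i+2 Cα distance
  6.7 Å, pleat amplitude chosen to keep 3.8 Å steps, strands 4.8 Å apart).
* `make_blob_protein()` — a self-avoiding random Cα walk (3.8 Å steps,
  3.2 Å minimum contact) confined to a sphere of radius
  $3.2\,n^{1/3}$ Å: a compact globule with no secondary structure.
* `make_descriptor_clusters()` — "folds" as clusters in descriptor space:
  centers on the non-negative orthant of a sphere of radius Δ (default 3),
  members perturbed by Gaussian noise clipped at zero. Each fold draws its
  own noise scale from $\sigma\cdot U(0.3, 2.5)$ around the base
  σ = 0.15. The heteroscedasticity is the point: real folds differ widely
  in how much surface variability their members show, and exactly this
  regime is where one global distance threshold on raw descriptors
  underperforms a learned pair comparator — the qualitative ordering the
  package's acceptance benchmark reproduces at desk scale (network
  held-out pair accuracy ≈ 0.99 against ≈ 0.84 for the best fixed
  threshold on the direct score). Homogeneous clusters
  (`noise_spread = c(1, 1)`), where both methods saturate, remain
  available for the unit tests that need clean separability.
* `make_plddt_profile()` — constant-level runs with optional jitter that
  never crosses the 70.0 boundary, so layout ground truth is exact.

What these generators do *not* emulate: real fold geometry, descriptor
correlation structure of real surfaces, length-dependent descriptor
scaling, or SCOPe's label noise. A passing benchmark here demonstrates
that the machinery — descriptor computation, training, thresholding,
retrieval — behaves correctly in a controlled regime; it does not certify
accuracy numbers on any real database, which would require the curated
fold assignments and trained weights of a production service.

## Problem sizes and numerical choices

Tests and the acceptance script use $N = 64$ grids, order 20, fixtures of
10–60 residues, ten synthetic folds of twenty members, and a 20-epoch
training run — sizes chosen so the whole suite exercises every code path
in a few minutes on one core while every tolerance stays meaningfully
tight (rotation invariance is calibrated at $N = 64$; production
descriptors default to $N = 200$). Degenerate inputs are handled by
erroring early and specifically: empty structures, non-protein atom sets
under `main_chain`, empty voxel grids, unnormalized fields, single-class
training data, zero-denominator metrics, catalogue folds without names.
Ties are always broken deterministically (occupancy strict `<`, search by
id, voting by summed probability then lexicographic order), so every
pipeline is bit-reproducible given its seed.

## Known limitations

* The surface is an offset iso-surface, not a rolling-probe SES; vertex
  and face counts are internally consistent but not numerically comparable
  to other surface generators, so the mesh-count features only carry
  information within an index built by this package.
* Descriptor values depend on the normalization conventions (scale margin
  0.6, basis normalization, voxel-volume quadrature weight); numeric
  identity with other 3DZD implementations is not expected, only
  equivalence up to their own conventions. In particular, fixed decision
  thresholds on the direct score (the 0.1 default carried from the
  retrieval literature) are scale-convention-bound: on descriptors
  computed by this package they should be recalibrated on labeled pairs,
  exactly as the acceptance benchmark does when it picks the
  best-accuracy threshold. Rankings, which the search relies on, are
  unaffected.
* The geometric secondary-structure assigner is a Cα heuristic; for
  publication-grade content fractions substitute a full assigner and pass
  the fractions in directly.
* The network trains on descriptor vectors of any origin but has no
  pretrained weights; users must train on their own labeled pairs (the
  `train` CLI subcommand) before `nn`-method search.
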