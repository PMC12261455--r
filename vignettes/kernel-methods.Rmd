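---
title: "3D graph kernels for molecules: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D graph kernels for molecules: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mol3dkern)
```

## The problem

Ligand-based virtual screening asks: given small molecules of known
activity against a target, rank new candidates by structural similarity.
Kernel machines handle this well on the small, expensive datasets typical
of bioassays, provided one has a positive semidefinite similarity between
molecular graphs. Classic 2D graph kernels see only atom labels and bond
topology; the geometry that governs binding — bond lengths, bond angles,
torsion angles — is invisible to them. This package computes graph kernels
that incorporate exactly those three geometric quantities while remaining
invariant to rigid motions of the conformer, because every geometric
feature is derived from pairwise inter-atomic distances only.

A molecule here is `G = (V, E, Z, l)`: atoms `V` with element-symbol
labels `l`, bonds `E` as undirected unlabeled edges, and 3D coordinates
`Z` in Angstrom. Bond orders and charges are read from SDF input and
discarded; none of the kernels use them.

## The GraphHopper weight machinery

All four kernels share one combinatorial core. For a graph with discrete
diameter $\delta$ (number of *nodes* on the longest shortest path, so an
edge has length 2), each node $v$ gets a $\delta\times\delta$ occurrence
matrix $M(v)$ whose $(i,j)$ entry counts the shortest paths of length $j$
on which $v$ sits at position $i$. The kernel between two graphs is

$$K(G,G') = \sum_{v\in V}\sum_{v'\in V'} w(v,v')\,k_n(v,v'),
\qquad w(v,v') = \langle M(v), M(v')\rangle,$$

with $\delta$ taken as the larger of the two diameters and matrices
zero-padded (padding never changes the inner products). Two counting
conventions needed fixing:

* **All tied shortest paths are counted**, not one representative per node
  pair. Picking one path per pair depends on traversal order; counting all
  of them is deterministic and is what the enumeration definition of
  $w$ implies. The brute-force oracle `brute_force_weights()` enumerates
  every shortest path explicitly and agrees exactly with the fast
  pipeline.
* **Trivial single-node paths are excluded by default.** A length-1 path
  carries no hop structure; `include_trivial_paths = TRUE` restores them
  (it adds 1 to entry $(1,1)$ of every $M(v)$).

Internally `M(v)` is assembled from the identity that $v$ lies at position
$i$ of a shortest $s{\to}w$ path of length $j$ iff
$d(s,v)=i-1$, $d(v,w)=j-i$ and $d(s,w)=j-1$, contributing
$N(s,v)\cdot N(v,w)$ such paths, where $N$ is the all-pairs
shortest-path-count matrix. Distances and counts come from level-wise
matrix products, which keeps the computation in vectorized linear algebra
rather than per-source graph traversals; the two formulations are
equivalent and the test suite pins the equality against the enumeration
oracle.

## 3D features from distances

For four consecutive bonded atoms A–B–C–D, six pairwise distances
determine the full local geometry. The bond angle at B follows from the
law of cosines. For the torsion angle, write $\theta_1,\theta_2$ for the
bond angles at B and C, $\rho_A = d_{AB}\sin\theta_1$ and
$\rho_D = d_{CD}\sin\theta_2$ for the perpendicular offsets of A and D
from the B–C axis, and $x_A, x_D$ for their axial positions; expanding
$d_{AD}^2$ gives

$$\cos\varphi = \frac{\rho_A^2+\rho_D^2+(x_A-x_D)^2-d_{AD}^2}
{2\rho_A\rho_D},$$

which `torsion_cos_distances()` evaluates from the six distances alone.
`torsion_cos_vector()` is the independent cross-product (plane-normal)
dihedral used to validate it; the two agree to about $10^{-13}$ on random
non-degenerate quadruples. Conventions: a planar *cis* chain gives
$\cos\varphi = +1$, *trans* gives $-1$. When a bonded triple is collinear
the torsion is geometrically undefined; the function reports
`defined = FALSE` rather than raising or returning NaN, so downstream
code chooses a policy explicitly.

The kernels do not use $\cos\varphi$ directly. Each 3-hop path gets a
similarity-matrix pipeline: $d$ is the $4\times4$ distance matrix,
$A = \exp(-d)$ entrywise, $A^1 = A\odot Adj$ masks $A$ with the fixed
chain adjacency, $A^2 = (A^1)^2 \oslash A$ and $A^3 = (A^2 A^1)\oslash A$,
where $\oslash$ divides off-diagonal entries and zeroes the diagonal
(self-interaction carries no information). The pipeline has closed-form
entries,

$$A^2_{AC} = e^{-(d_{AB}+d_{BC}-d_{AC})},\qquad
A^3_{AD} = e^{-(d_{AB}+d_{BC}+d_{CD}-d_{AC}-d_{AD})},$$

so $A^2$ encodes bond angles (the exponent vanishes exactly when the
triple is collinear) and $A^3$ is a linear-in-distances surrogate for the
torsion. The 13-entry motif feature is: 4 labels, 6 distance similarities
$e^{-d}$ for all pairs, $A^2_{AC}$ and $A^2_{BD}$, and
$A^3_{AD}+A^3_{DA}$. The six distance entries deliberately use the
*unmasked* $A$ — masking with $Adj$ would zero the three non-bonded pairs
and waste a third of the feature — and the same nine continuous values
feed both 3D kernels, so there is exactly one featurizer.

Distances are used in Angstrom as read, with no normalization before
exponentiation; $e^{-d}$ then lives in $(0,1]$ for any physical geometry.
Degenerate inputs (coincident non-bonded atoms) give similarity 1 and are
allowed.

## The two 3D kernels

**Chain-motif graph kernel (`cmgk`).** Build the *c-motif graph*: one
node per directed 3-hop path, an edge whenever two motifs share at least
one atom (read literally; overlap size is not weighted), then run the
GraphHopper kernel on this derived graph. The motif node kernel is a
Dirac gate on the label *multisets* times the dot product of the nine
continuous features. The multiset reading makes a motif match its own
reversal, which is the natural choice given that both directions of every
chain are kept; `dirac = "ordered"` is available for the stricter
path-order comparison, and `dedupe_reversed = TRUE` collapses the two
directions. A molecule with no 3-hop path (fewer than four atoms in a
row, e.g. a star) has an empty motif graph and kernel value 0 against
everything.

**3D GraphHopper kernel (`3dghk`).** Keeps the weights on the *original*
molecular graph and moves the 3D information into the node kernel: a
Dirac gate on the two atom labels times, over all pairs of 3-hop paths
starting at the two atoms whose *ordered* label 4-tuples agree, the dot
product of their features. Ordered matching is forced here because the
objects being compared are directed paths; "same atoms" across molecules
can only mean same element labels in sequence. Because the path kernel is
linear, the double sum over matching pairs factorizes into dot products
of per-label-key feature sums, which is what makes this kernel fast.

The baseline `ghk2d` is the label-Dirac GraphHopper kernel (no
coordinates at all), and `3dghk_2hop` is an ablation that replaces the
3-hop featurization by its 2-hop analogue: 3 labels, 3 distance
similarities, 1 bond-angle similarity from the $3\times3$ pipeline. It
exists to measure what the third hop (and with it the torsion term)
contributes; the package reports that comparison but does not hard-code
an expected ordering, which is an empirical matter.

Every kernel is a sum of $w(v,v')\times$ (Dirac $\times$ linear) terms
with $w$ itself an inner product, hence positive semidefinite by
construction; `gram_min_eigen()` provides the numerical check (the test
suite requires the minimum eigenvalue to stay above
$-10^{-8}\times\mathrm{trace}$).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `hydrogens` | `"strip"` | Heavy-atom graphs are the norm for molecular graph kernels and keep the maximum degree small; `"keep"` retains explicit H. |
| `include_trivial_paths` | `FALSE` | Single-node shortest paths in $w$. |
| `dirac` | `"multiset"` | Motif label gate for `cmgk`. |
| `dedupe_reversed` | `FALSE` | One motif per undirected chain instead of two. |
| `normalize` | `FALSE` | Cosine normalization of the Gram matrix. Raw values grow with molecule size; normalization is strongly recommended before SVM training when molecule sizes vary (see below). |

On normalization: the kernels are exactly block-diagonal across molecules
with disjoint label alphabets, but *within* a block the unnormalized
values span orders of magnitude, and same-class molecules that share no
matching label tuple have entry 0. An SVM on such a raw Gram matrix can
fail to reach perfect accuracy even on separable data; cosine
normalization removes the scale component and is cheap.

## The screening harness

`evaluate_kernel()` reproduces a standard virtual-screening protocol:
per repeat, subsample the inactives down to the active count (bioassay
sets are heavily unbalanced), split 70/15/15 stratified by class, train a
precomputed-kernel SVM (kernlab) for each cost in
`C ∈ {0.001, …, 1000}`, select `C` on validation accuracy (ties to the
smallest `C`, favoring the wider margin), and score the selected model on
the untouched test block. Splits are stratified because an unstratified
15% block of a small balanced set loses a class entirely often enough to
matter. Reported spread is the sample SD ($n-1$) over repeats. Each
repeat re-draws the balanced subsample by default (`rebalance = FALSE`
freezes it). The harness never consults test labels before final scoring.

`compare_kernels()` is the paired two-sided Wilcoxon signed-rank test on
per-dataset accuracies, zero differences dropped. Accuracy differences
across datasets are routinely tied, and the textbook exact distribution
is unavailable under ties, so for up to 14 informative pairs the p-value
is computed by exact enumeration of all $2^n$ sign assignments of the
(mid)ranks — which coincides with the classical exact test when there are
no ties — and the normal approximation is used beyond that.

## Synthetic molecules and what the tests do (and do not) show

`sample_molecule()` grows a random spanning tree (each atom attaches to a
uniformly chosen earlier atom at 1.5 Angstrom in a uniformly random
direction) and closes rings with a small per-pair probability (default
0.02; fixtures that need cyclic structure raise it). This emulates the
*statistics the kernels consume* — realistic bond lengths, connected
graphs of 8–25 heavy atoms, a few percent ring bonds, a C/N/O-dominated
label alphabet — and deliberately not chemistry: valences are unchecked,
bond angles are unconstrained, and conformers are not energy-minimized.
Tests on these fixtures therefore establish the *mathematical* contracts
(closed forms, oracle equality, PSD-ness, invariances, harness behavior)
on inputs of realistic size and composition; they say nothing about
classification accuracy on real bioassay data, which depends on chemistry
the generator does not model.

Problem sizes used by the test suite and the acceptance script — 1000
random quadruples for the torsion identity, 500 paths for the closed
forms, 200 graph pairs (≤ 8 nodes) for the enumeration oracle, 30
molecules of 8–25 atoms for Gram validity, 20 molecules × 20 rigid
transforms for invariance, 24-molecule screening toys with 20 repeats —
were chosen so each property is exercised well past its edge cases while
the whole suite stays comfortably runnable on a laptop.

## Numerical choices and degenerate inputs

* Cosines within $10^{-9}$ of $\pm1$ are clamped; drift beyond that
  raises an error, since it signals distances that are not realizable in
  3D rather than floating-point noise.
* Torsions on collinear triples are flagged `defined = FALSE`
  (see above); the kernel pipeline never hits this because it uses the
  $A^3$ surrogate, which is finite for all geometries.
* Path enumeration, motif ordering and Gram assembly are all sorted
  lexicographically, so every derived object is reproducible bit for bit.
* All randomness (generators, splits, subsampling) is seeded through
  `withr::with_seed`, leaving the caller's RNG state untouched, and
  repeat $r$ of the harness derives seed `seed + r`.

## Known limitations

* Distance-only features cannot distinguish a conformer from its mirror
  image: enantiomers get identical kernel values. This is asserted in the
  test suite as a documented property, not a defect to be fixed within a
  distance-based design.
* The torsion entry is a smooth surrogate, not $\cos\varphi$ itself; two
  quadruples can share the surrogate value while differing in true
  torsion.
* Kernel cost grows with the number of 3-hop paths, i.e. roughly with
  $nT^3$ for maximum degree $T$; highly branched graphs make the
  chain-motif graph (and `cmgk`) substantially more expensive than
  `3dghk`, which is the point of having the latter.
* 2D SDF records (all-zero z) are accepted with a warning, but their "3D"
  features are meaningless; strip them or re-embed upstream.
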