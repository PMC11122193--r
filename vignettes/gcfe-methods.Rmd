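---
title: "Gershgorin circle feature extraction: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gershgorin circle feature extraction: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfe)
```

## The model

GCFE treats an image patch as a weighted graph and summarizes the
spectrum of its Laplacian without computing it. For a p × p patch the
Z = p² pixels are nodes (row-major order), and an edge (i, j) carries
weight $W_{ij} = |v_j - v_i|$, the absolute difference of the normalized
intensities. Three graph topologies are supported: the 4-connected grid
lattice, the complete pairwise graph, and a K-nearest-neighbour graph in
intensity space.

The key construction is the *modified weighted Laplacian*
$L = D - A$: $A$ is the weighted adjacency, but $D$ holds the
*unweighted* degrees — the edge counts from the binary adjacency $S$.
Because every weight satisfies $W_{ij} \le 1$ while each edge
contributes exactly 1 to $D_{ii}$, every row obeys

$$L_{ii} = \deg(i) \;\ge\; \sum_{j \ne i} |L_{ij}| = \sum_{j \sim i} W_{ij},$$

with strict inequality whenever any incident weight is below 1. A
symmetric, weakly diagonally dominant matrix with nonnegative diagonal
is positive semi-definite, so the Gershgorin interval of row i — center
$c_i = L_{ii}$, radius $r_i = \sum_{j\ne i}|L_{ij}|$ — lies on the
nonnegative real axis, and the union of the Z intervals contains every
eigenvalue of $L$. The pair of vectors $(R, C)$ is the feature: a
P × N × 2 array (P patches, N = p² nodes) totalling 2MN values for an
M × N image, *whatever* patch size is chosen.

Equality $c_i = r_i$ occurs exactly when every neighbour of pixel i
differs from it by the full intensity range (pure black against pure
white). The package therefore asserts weak dominance universally and
strict dominance conditionally; a blanket "strictly dominant" claim
would fail on such saturated patches, which the test suite constructs
deliberately.

## Parameters that matter

* **`patch_size` (p).** Must divide both image dimensions; the error
  message lists the valid divisors. Smaller p gives more, smaller
  Laplacians; the feature *count* is unaffected (2MN always), but the
  feature *content* changes — grid and KNN graphs see less context per
  patch.
* **`graph_type`.** `grid2d` keeps L maximally sparse (degree ≤ 4) and
  encodes spatial adjacency; `pairwise` makes every center equal to
  Z − 1 so all information moves into the radii; `knn` interpolates,
  with structure driven by intensity similarity rather than position.
* **`knn_k`.** Defaults to `patch_size`, the convention used in the
  original K-NN evaluations. Valid range 1 … Z − 1; at Z − 1 the KNN
  graph equals the pairwise graph.
* **`grayscale`.** RGB inputs are reduced to Rec. 601 luminance
  (0.299 R + 0.587 G + 0.114 B, rounded) before normalization, because
  edge weights require scalar pixel values. How colour should enter the
  weight function is genuinely open; luminance is this package's
  documented choice, made once.

## Numerical and convention choices

* **Normalization is fixed-range** (`x / 255`), not per-image min/max:
  per-image scaling would make identical patches from different images
  incomparable and would break the [0, 1] weight bound the dominance
  argument rests on.
* **Orders.** Patches are traversed row-major over the patch grid and
  pixels row-major within a patch; both are raster conventions applied
  consistently, and `stitch_patches()` inverts partitioning bit-exactly.
* **KNN metric and ties.** Neighbourhoods are computed on $|\Delta v|$
  (intensity is the only node attribute the model defines), ties broken
  by ascending node index, and the directed picks symmetrized by union.
  Any other deterministic tie rule would be equally defensible; this one
  is the simplest to reason about and is frozen in tests (a constant
  patch with k = 1 yields a star on node 1).
* **Zero-weight edges** between equal-valued pixels are structural: they
  contribute to degrees (centers) but not to adjacency mass (radii).
  This asymmetry is the entire point of the modification and gets a
  dedicated regression test.
* **1D layout order.** The flattened feature vector interleaves
  [R₁, C₁, R₂, C₂, …] so each patch's two vectors stay adjacent; a
  `blocked` alternative (all radii, then all centers) is available. The
  2D layout is the two-row plane (2, P·N, 1): radii row over centers
  row.
* **Pooling convention.** In the CNN specs, average pools use *stride
  equal to the pool kernel in each dimension* with valid padding, so a
  (1 × 2) pool halves only the width and a (2 × 2) pool floors both
  dimensions. This is the framework default for pooling layers and is
  the only convention under which the published model sizes —
  3,504,879 parameters for GC-feature input and 38,841,263 for the
  patch-14 Laplacian stack — are reproduced exactly; a literal stride-2
  on both axes of the (1 × 2) pool would collapse the two-row plane.
  Exact integers are the source of truth; the ×10⁻⁶ figures are
  rounded for display.
* **Reporting statistics.** `sample_sd()` uses the n − 1 denominator
  and `pct_diff()` the symmetric mean-denominator convention; both were
  chosen because they reproduce all six published dispersion/difference
  figures, where the population SD and relative-to-baseline forms do
  not. `z_score()` is the standard definition only — the published
  *averaged* Z-scores are not derivable from the printed data, so no
  aggregation is offered.
* **Tolerances.** PSD is asserted as λ_min ≥ −1e−9 (dense symmetric
  eigensolver); interval membership uses the same 1e−9 slack; exact
  integer identities (trace = 2|E|, edge counts, degrees) are asserted
  without tolerance.

## What the synthetic fixtures do and do not show

`synth_image()` generates constant, checkerboard, gradient, and seeded
uniform-random images; `fig_sample_4x4()` is a fixed random 4 × 4 sample
used for hand-checkable walkthroughs (its published counterpart's pixel
values were never printed, so only structurally forced facts are
asserted about it: pairwise 2 × 2 centers all 3, radii ≤ 3). These
fixtures exercise every code path — degenerate constant patches,
saturated 0/255 contrasts, duplicate values, full-range randomness — but
they are not natural images: they have no spatial autocorrelation,
texture, or class structure. Passing tests certify the algebraic
contract of the extraction (inclusion, dominance, shapes, determinism),
not classification performance on real data.

Test and verification problem sizes: random patches span sizes 2–8
under all three graph types (the invariant suite checks 210 patches,
eigendecomposing matrices up to 64 × 64), and end-to-end extractions use
28 × 28 and 8 × 8 images across all valid patch sizes. These sizes make
every invariant checkable by dense eigensolver in seconds while covering
the whole divisor lattice of the 28 × 28 case.

## Design decisions that were genuinely open

* **Grid connectivity.** "2D-grid lattice" is implemented as
  4-connectivity (von Neumann): it is the standard grid-graph reading
  and keeps L sparsest; 8-connectivity would be defensible but changes
  every degree and was not adopted.
* **Laplacian stacking for the comparison CNN.** The P per-patch N × N
  Laplacians are concatenated vertically into a (P·N, N, 1) plane — the
  only arrangement consistent with the published patch-14 and patch-28
  model sizes. Published sizes for patches 2, 4, and 7 are not
  reproducible under any stacking/pooling convention tried (patch 2
  even pools a dimension to zero, which the spec builder rejects with
  an error); they are excluded rather than force-fitted.
* **Training harness.** Fitting the CNNs is out of the package's core:
  `train_and_evaluate()` probes for a deep-learning backend (keras or
  torch) and raises a classed capability error when none is installed,
  so feature extraction and parameter accounting never depend on one.
  The deterministic split arithmetic (70/15/15 → 700/150/150 on 1000
  samples) lives in `split_indices()` and is tested.
* **Benchmark table hygiene.** The bundled accuracy table flags the
  pairwise spectral-embedding value 95.86 at E_Balanced patch 4 as
  anomalous (inconsistent with every neighbouring entry) and excludes it
  from all series; out-of-memory cells are `NA`.

## Known limitations

* GCFE is irreversible: (R, C) does not determine L, and no
  reconstruction is attempted.
* Features are eigenvalue *bounds*, not eigenvalues; tighter inclusion
  regions (Brauer ovals and other refinements) are out of scope.
* The pairwise graph makes centers constant within a patch size, so all
  discriminative signal rides on the radii.
* Colour handling is a fixed luminance reduction; channel-aware weights
  are not modelled.
* The CNN specs are declarative: shapes and parameter counts are exact,
  but no training or inference is performed without an optional
  backend.
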