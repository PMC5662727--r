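---
title: "Stereological soma counting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereological soma counting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somascope)
```

## The problem

Counting a specific neuron type across a brain volume from fluorescence
stacks is classically done in two dimensions: tissue slabs are
maximum-intensity-projected and cells counted per projection. Because the
projection has no axial resolving power, somas that are disjoint but
aligned along the optical (z) axis merge into one blob and are
under-counted, and cells sitting on slab interfaces can be counted twice.
Stereological counting — detecting every soma in the full 3D volume —
avoids both biases. `somascope` implements the full desk-scale chain:
synthetic phantoms with known ground truth, foreground extraction, sparse
soma localization, 3D-vs-planar comparison, morphometry, per-region
densities, and the associated statistics.

## The localization model

Somas are sparse, compact, and roughly ball-shaped; neurites are thin and
elongated. The localizer exploits exactly this contrast:

1. **Foreground extraction.** The stack is binarized (Otsu on the
   full-stack 256-bin histogram by default, or a fixed threshold), eroded
   with a 6-connected structuring element, and 26-connected components
   below a minimum size are dropped. Erosion detaches ~1 um-thick
   neurites from somas and the size filter discards them, so the later
   fit sees mostly ball-like foreground.
2. **Candidate seeding.** Candidates are local maxima of the
   anisotropy-aware Euclidean distance transform of the mask, computed in
   micrometres so a 2 um z-step is treated as 2 um, not one voxel.
   Maxima closer than 2 um merge to their centroid. Every surviving
   foreground component contains its interior distance maximum, so no
   component is missed.
3. **Sparse L1 ball superposition.** For every candidate `c` and every
   radius `r` in a discrete set, a unit-normalized ball indicator
   `phi_{c,r}` is rasterized on the anisotropic grid. With `f` the binary
   foreground (as 0/1 reals) the fit solves

   $$\min_{w \ge 0} \tfrac12 \Big\| \sum_i w_i \phi_i - f \Big\|^2
     + \lambda \|w\|_1$$

   by proximal gradient descent (ISTA) with non-negativity projection.
   The fit target is the binary foreground rather than raw intensity:
   the model describes occupancy, and binarized targets make atom
   normalization scale-free. Each candidate keeps its single best-weight
   radius (a soma is one ball; mixtures would double-count), weights
   below `weight_min` are dropped, and greedy weight-descending
   non-maximum suppression enforces a minimum centre separation.

The objective is convex; with step `1/L`, where `L` is the largest row
sum of the absolute Gram matrix (an upper bound on the Lipschitz constant
of the gradient), the objective is provably non-increasing — the test
suite asserts this per iteration.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `radius_set_um` | 2, 3, 4, 5, 6, 8, 10 | um | spans the 3–10 um semi-axis range of labelled interneuron somas |
| `lambda` | `0.1 * max(phi' f)` | — | scale-relative: a tenth of the best atom's correlation with the foreground |
| `weight_min` | 0.2 | — | rejects atoms that explain almost nothing (a perfectly covered ball of `m` voxels attains weight ~ `sqrt(m)` >> 1) |
| `merge_dist_um` | 8 | um | about one soma diameter; ties broken by lexicographic centre order, so suppression is deterministic |
| `max_iter` / `tol` | 500 / 1e-4 | — | relative objective-change stop; typical fits converge far earlier |
| erosion | 1 pass, 6-connected | voxels | voxel-space operation (not isotropic in um), the common practice on anisotropic stacks |
| `min_component_voxels` | 20 | voxels | well below a r = 5 um soma (~260 voxels at 1 x 1 x 2 um), well above neurite fragments |

None of these are published values; they are this package's defaults,
exposed in `l1Config()` and `preprocessConfig()`.

## Block-wise processing

Whole-brain stacks do not fit in memory, so the volume is tiled into
half-open cores (nominally 512 x 512 x 512 um) that partition the voxel
grid exactly once. Each core is processed with a surrounding halo —
default 40 um, twice the largest expected soma diameter — and a
detection is kept only by the block whose core contains its centre
(half-open ownership). That rule makes seam-straddling somas belong to
exactly one block, and with an adequate halo the block-wise result
matches the whole-volume run one-to-one (asserted within 3 um in the
tests).

## Planar counting emulation

`countCells2DProjection()` partitions z into 50 um slabs,
maximum-intensity-projects each, and reuses the same pipeline in 2D (2D
Otsu, 4-connected erosion, 2D distance-transform maxima merged at the
same `merge_dist_um`). Reusing the 3D parameters in 2D is deliberate: it
isolates the dimensionality effect, which is the quantity of interest
when comparing the two counting modes.

## The phantom generator

The generator emulates the labelled-soma channel of a high-resolution
anisotropic dataset: ellipsoidal somas with semi-axes jittered around
(6, 5, 4) um, rotated in-plane; a neocortex-like default density of
10,000 somas/mm^3; a 12 um centre-to-centre exclusion; a configurable
fraction of *axial pairs* — two disjoint somas stacked along z with a
2–6 um surface gap, the configuration that planar counting merges;
random-walk neurite tubes (0.5–1 um radius) at an intensity midway
between background and soma, to exercise the claim that the L1 model is
robust to neurite clutter; soma level 200 over background 10 with
additive Gaussian noise (sigma 5) on an 8-bit scale. Rasterization
anti-aliases ellipsoid boundaries by 2x2x2 partial-volume subsampling,
because hard-thresholded balls are visibly blocky at a 2 um z-pitch.
Placement is rejection sampling capped at 10,000 attempts per soma;
failure raises an error naming the achieved count rather than silently
returning fewer cells.

What the phantom does **not** model: optical point-spread, Poisson
(shot) noise, photobleaching, stitching seams, counterstain channels,
and realistic neurite morphology. Passing tests therefore demonstrate
algorithmic correctness under a clean forward model, not performance on
real tissue; published whole-brain totals cannot be reproduced at desk
scale and are replaced by ground-truth-based properties (recall and
precision at least 0.95 on a 512^3 um phantom, exact 3D counts at
moderate density, 3D > planar in the presence of axial pairs).

## Morphometry definitions

Published morphometric comparisons use "longest and shortest radii",
surface area and volume without defining the radii. This package defines
them as **principal-axis half-extents**: eigenvectors of the coordinate
covariance of the segmented mask give the axes; the radius along an axis
is half the projected extent plus half the voxel footprint at each end
(voxel centres alone under-measure the physical extent by about one
voxel). This choice is rotation-invariant and matches the ovoid/spindle
description of interneuron cell bodies; Feret diameters or fitted
ellipsoid axes would be defensible alternatives. The average radius is
the arithmetic mean of the three half-extents, and the ratio is
longest/shortest exactly.

Surface area is estimated by counting exposed voxel faces. This is
deterministic and mesh-free but overestimates smooth surfaces: for a
sphere the continuum limit of the face-count is 1.5x the true area (the
integral of the L1 norm of the surface normal), and at a 1 um pitch the
measured bias for a r = 5 um sphere is about 1.55–1.6x. The estimator is
therefore useful for *comparisons between regions*, not as an absolute
area; the tests pin the bias envelope.

Segmentation is region growing from the detection centre, admitting
voxels above half the centre-neighbourhood mean intensity and stopping
at a hard 15 um ball. A centre voxel darker than that threshold flags a
mislocalized detection as an error; in batch mode (`morphologyTable()`)
such somas are skipped with a warning.

## Evaluation statistics

Matching detections to truth uses the Hungarian algorithm on the
thresholded distance matrix (default radius 5 um, about one soma
radius): optimal, deterministic, order-independent, and strictly better
than greedy matching in crossed configurations (the tests compare
against exhaustive enumeration). Recall is `B/B1` and precision `B/B2`
with B1 the true/manual count, B2 the automatic count, B the matched
count, reported as exact ratios — note that a matched 57 of 59 yields
precision 0.9661, which prints as 96.6%, not 96.7%.

The 3D-vs-planar comparison uses the Wilcoxon signed-rank test with
`W = min(W+, W-)`. The default mode is the normal approximation
*without* continuity correction, `z = (W - n(n+1)/4) /
sqrt(n(n+1)(2n+1)/24)`, because that is the mode legacy statistics
packages report and the one that yields p = 0.043 for five cubes in
which 3D counting exceeds planar counting in every cube. Exact
enumeration of all `2^n` sign patterns is available for n <= 20 and
returns 0.0625 on the same data — the minimum achievable two-sided
exact p at n = 5 — which is precisely why the approximation mode is the
reproduction default. For n in 15–20 the two modes agree to within
about 0.03 (worst case, measured by simulation; typical deviations are
far smaller). The normal-mode variance carries no tie correction;
midranks are still used for tied absolute differences.

Group comparisons (morphology across regions, brightness across
datasets) use classical one-way ANOVA via `stats::aov()`.

## Numerical and convention choices

* Coordinates are physical micrometres everywhere outside raw arrays;
  arrays are `(nx, ny, nz)` column-major; voxel centres sit on integer
  multiples of the pitch; ownership intervals are half-open (a point
  exactly midway between voxel centres belongs to the upper voxel).
* Erosion treats out-of-volume voxels as background; degenerate axes of
  extent 1 are skipped so single-slice arrays erode with the 2D
  4-connected element.
* Otsu refuses constant-intensity stacks (no separable classes); a
  featureless projection slab counts zero cells instead of erroring.
* The distance transform is the exact separable lower-envelope
  algorithm with per-axis spacing, so anisotropy is handled without
  resampling.
* SWC output is a soma-only dialect: one parentless type-1 node per
  cell, three decimals, micrometres. Reading and writing round-trips
  bitwise.
* TIFF stacks require a JSON sidecar stating the voxel size; a missing
  sidecar is an error, never a guessed default.
* All randomness (phantom generation, sampling for brightness
  comparisons) flows through explicit integer seeds; localization
  itself contains no randomness, so seeded end-to-end runs are
  bit-reproducible.

## Problem sizes

The test suite runs phantoms from 80^3 um (single-soma analytic checks)
up to one 512 x 512 x 512 um volume at 1 x 1 x 2 um (512 x 512 x 256
voxels, ~1,340 somas at the default density), the size used for the
recall/precision property; that case takes well under a minute on a
single core. Larger volumes are intended to go through
`locateSomasBlockwise()`, which was validated against whole-volume runs
on multi-block phantoms.

## Known limitations

* The surface-area estimator's systematic overestimation (above).
* Radius estimates are quantized to the configured radius set and biased
  slightly low because the fit target is the eroded foreground.
* Planar counting is an algorithmic emulation; published planar counts
  obtained by human annotators could differ.
* The region atlas generator produces slab partitions — adequate for
  density arithmetic, not for realistic region geometry.
* Densities beyond ~15,000 somas/mm^3 with touching somas are outside
  the validated regime of the default configuration.
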