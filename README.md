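# somascope

Stereological (full-3D) detection, counting and morphometry of
fluorescently labelled neuronal somas in anisotropic image stacks.

## The problem

Quantifying a neuron type across brain tissue is traditionally done in
two dimensions: slabs of tissue are maximum-intensity-projected along
the optical axis and cells counted per projection. Projections have no
axial resolving power, so somas that are disjoint but aligned along z
merge into one blob and are missed, while cells on slab interfaces can
be counted twice. Counting in the full 3D volume removes both biases.
`somascope` is a desk-scale implementation of that stereological
pipeline for researchers working with 3D fluorescence stacks (and for
anyone who wants a fully synthetic, ground-truthed testbed for 3D cell
detection).

## The method

The localizer assumes somas are sparse, compact and approximately
ball-shaped, while neurites are thin and elongated:

1. **Foreground extraction** — binarization (Otsu by default), erosion
   with a 6-connected element, and removal of small 26-connected
   components; erosion detaches the ~1 µm neurites which the size filter
   then discards.
2. **Candidate seeding** — local maxima of the anisotropy-aware
   Euclidean distance transform (computed in µm), merged within 2 µm.
3. **Sparse L1 ball superposition** — with a dictionary of
   unit-normalized ball indicators φ<sub>c,r</sub> over candidates *c*
   and radii *r* ∈ {2,…,10} µm, solve

   min<sub>w ≥ 0</sub> ½‖Σ<sub>i</sub> w<sub>i</sub>φ<sub>i</sub> − f‖² + λ‖w‖₁

   for the binary foreground *f* by proximal-gradient descent, keep each
   candidate's best-weight radius, and apply weight-descending
   non-maximum suppression.

Large volumes are processed block by block (half-open cores with a halo
twice the largest soma diameter), a detection belonging to the single
block whose core contains its centre. Evaluation uses optimal Hungarian
matching, recall `R = B/B1` and precision `P = B/B2`, the Wilcoxon
signed-rank test (normal approximation or exact enumeration) for paired
3D-vs-planar counts, and one-way ANOVA for group comparisons. A phantom
generator produces seeded, bit-reproducible synthetic stacks with known
ground truth, including the z-aligned soma pairs that planar counting
merges.

## Worked example

```r
library(somascope)

spec <- phantomSpec(shape_um = c(120, 120, 100), n_somas = 10,
                    axial_pair_fraction = 0.6, seed = 3)
ph  <- generatePhantom(spec)     # stack + ground truth
det <- locateSomas(ph$stack)     # 3D localization
head(det, 3)
#>   id     x_um     y_um z_um radius_um   weight block
#> 1  1 11.31818 17.18182   32         4 3.665650    NA
#> 2  2 28.50000 36.50000   76         4 3.920061    NA
#> 3  3 36.00000 30.50000   20         4 4.414708    NA

evaluateDetections(det, ph$truth)
#> B1 (true) = 10, B2 (detected) = 10, matched B = 10
#> recall = 1.0000, precision = 1.0000 (match radius 5 um)

countCells3D(det)                                      # 10
countCells2DProjection(ph$stack, slab_thickness_um = 50)  # 8
```

All ten somas — six of them in three disjoint z-aligned pairs — are
found in 3D; planar counting of 50 µm projections merges two of the
pairs and reports only 8. That gap is the stereological bias the
package quantifies: on five paired cubes where 3D counting exceeds
planar counting throughout, `wilcoxonSignedRank()` in its
normal-approximation mode gives the two-sided p = 0.043.

Morphometry of the same detections:

```r
m <- morphologyTable(ph$stack, det)
summary(m[, c("longest_radius_um", "shortest_radius_um", "volume_um3")])
#>  longest_radius_um shortest_radius_um   volume_um3
#>  Median :6.259     Median :5.139      Median :536.0
```

consistent with the generated semi-axes of roughly 6 × 5 × 4 µm
(volume ≈ 500 µm³). A thin CLI is installed as `exec/somascope`
(`phantom`, `locate`, `evaluate`, `run` subcommands), and
`runPipeline()` drives the whole chain from a YAML config, writing
`somas.csv`, `somas.swc`, `morph.csv`, `regions.csv` and `report.json`.

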