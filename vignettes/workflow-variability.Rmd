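---
title: "Measuring workflow variability in segmentation-to-STL pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring workflow variability in segmentation-to-STL pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(segqa)
```

## The problem

Anatomical models for surgical planning are produced by a five-step digital
pipeline: image import, segmentation, surface meshing, smoothing/refinement,
and STL export. Each step is parameterized, and different software packages
make different choices at every one of them. The geometric spread between
final models produced by equally reasonable workflows is rarely quantified,
yet it directly bounds the trust one can place in any single model. `segqa`
implements that quantification end to end: it generates a controlled test
case, runs parameterized workflows over it, and measures the resulting
variation with global and local metrics plus the accompanying statistics.

This vignette documents the models and conventions the package commits to,
the parameters that matter, and what the test suite does and does not
demonstrate about real clinical data.

## The phantom: what it emulates and what it does not

Real cranio-maxillofacial scans cannot ship with a package, so the study
case is synthetic. `make_mandible_phantom()` builds, on a configurable voxel
grid:

* **A mandible-like arch** — a capsule swept along a circular arc (default
  centerline radius 22 mm, cross-section radius 7 mm, angular half-span
  110°), with a cortical shell (default 2 mm, 1200 HU) around a cancellous
  interior (300 HU).
* **A tumor** — a full analytic ellipsoid (default semi-axes 8 × 6 × 5 mm,
  60 HU) carved out of the arch. The ellipsoid is positioned so that its
  clearance to the outer arch surface equals the `residual_wall` parameter
  (default 0.8 mm): the bone left between tumor and outer surface is the
  thin-wall partial-volume challenge. Because the mandible mask is defined
  as *arch minus ellipsoid*, the tumor truth mask is exactly the analytic
  ellipsoid and the two masks are disjoint by construction.
* **Nerve canals** — tubes of radius 1 mm (20 HU) following a natural cubic
  spline through control points along the arch, with an optional sinusoidal
  z-undulation (default amplitude 1 mm, 2.5 periods). At 20 HU against
  40 HU soft tissue, the canals cannot be thresholded reliably — the reason
  the nerve workflow paints slices and interpolates instead.
* **Landmarks** — seven named fiduciary points (condyle, gonion, menton,
  alveolar-crest analogues and the tumor center) with five caliper pairs
  and their exact ground-truth distances.

Tissue intensities are plausible CT Hounsfield units chosen by us (air
−1000, soft tissue 40, nerve 20, tumor 60, cancellous 300, cortical
1200); they are package decisions, not reproductions of any scan, and all
are configurable. The default grid is anisotropic (0.33 × 0.33 × 1 mm) to
echo clinical CT geometry: sub-mm in-plane pixels with 1 mm slices.

Voxel model: membership is evaluated analytically at voxel centers; world
position of voxel `(i, j, k)` is `origin + (i−1, j−1, k−1) · spacing`. This
matches the iso-surfacing convention downstream, where the binary boundary
sits halfway between an inside and an outside center.

`degrade()` models the acquisition chain as Gaussian point-spread blur
(stated FWHM, separable, renormalized at borders so total intensity is
conserved), optional linear resampling to a coarser grid (refusing to
fabricate resolution), then additive Gaussian noise with a caller-supplied
seed. It reproduces the partial-volume direction: with a 1 mm FWHM blur the
0.8 mm residual wall loses thresholded bone voxels (about 7% at the default
grid), the same failure mode that makes thin cortex adjacent to tumors the
hardest region for real workflows. The phantom deliberately omits scanner
physics — no beam hardening, metal artifact, or reconstruction-kernel
effects — so passing tests show that the *pipeline mathematics* is correct
and that the *direction and ranking* of workflow effects is as expected,
not that any absolute disagreement percentage will transfer to a given
clinical scan.

## Segmentation operators

* `threshold_mask()` uses inclusive bounds on both ends; inclusivity is a
  convention we fixed since the boundary voxels of a discrete HU histogram
  have to land somewhere deterministic.
* `region_grow()` is threshold + connected components restricted to
  seed-containing components. Default connectivity is 26; configurable
  since tools differ and rarely document it.
* `apply_morphology()` uses Euclidean-ball structuring elements with radii
  in voxels. Erosion treats out-of-grid neighbors as foreground — the
  adjoint convention for grid-clipped dilation. This is not cosmetic: with
  the adjoint pair, open and close are genuine algebraic openings/closings
  and their compositions are idempotent filters (the property the test
  suite asserts); with the naive all-background convention idempotence
  fails at grid borders. `keep_largest` breaks ties toward the component
  whose first voxel comes earliest in (z, y, x) raster order, making
  results reproducible on tied inputs.
* `interpolate_slices()` does shape-based interpolation: linear blending of
  the two neighboring slices' signed in-plane Euclidean distance fields,
  thresholded at zero. Distance-field interpolation is the de-facto
  standard for "connect the painted slices" tools and, unlike morphological
  interpolation, has an exact small-case oracle (two concentric disks
  interpolate to the mid-radius disk). The distance transform is exact
  (Felzenszwalb's lower-envelope algorithm) and computed in pixel units;
  anisotropic in-plane grids trigger a warning.

## Surface extraction

`extract_surface()` contours the 0/1 indicator field at iso-level 0.5 after
padding the mask with one background layer, so surfaces always close.
Iso-surfacing runs on a conforming tetrahedral decomposition of the voxel
lattice (the Freudenthal 6-tet split, every cell sharing the same main
diagonal). We chose marching tetrahedra over classic cubes for two reasons:
every tetrahedral sign pattern is unambiguous, so no lookup-table
disambiguation is needed and watertightness holds by construction; and
every surface vertex lies on a unique lattice edge, letting the
implementation key vertices by edge and rebuild exact shared connectivity.
The cost is a denser tessellation — roughly 2× the triangles of classic
marching cubes — and, as with any staircase tessellation of a binary field,
a surface-area overestimate (about 27% on a rasterized ball). Enclosed
volume, by contrast, converges quickly: 0.4% error on a 20-voxel-radius
ball, second order in spacing. Area comparisons between models carry the
same tessellation bias on both sides and remain meaningful as comparisons;
absolute areas of rasterized masks should not be read as anatomical truth.
Meshing the grayscale volume directly was deliberately excluded:
segmentation defines the boundary, and mixing the two would attribute
intensity effects to the mesher.

## Smoothing and decimation

`laplacian_smooth()` is the canonical umbrella-operator form: uniform
weights over the 1-ring, synchronous updates, step `lam` ∈ (0, 1]. On
closed convex meshes volume shrinks monotonically per iteration — asserted
as a property test. `taubin_smooth()` alternates `lam` with a negative `mu`
step, enforcing the pass-band window `0 < lam < 1`, `−1 < mu < 0`,
`|mu| > lam`. At the default (0.33, −0.34)
and 50 iterations, volume drift on a 5120-face icosphere is 0.41% while the
pure Laplacian run shrinks 13.2%. The drift bound is asymptotic in mesh
resolution (a 320-face icosphere drifts 3.2%): the pass-band argument
treats the mesh as sampling a smooth surface, so the property is tested on
the finer fixture. The "smooths comparably" claim is tested as roughness
removal — both smoothers cut the radial roughness of a noise-perturbed
icosphere by more than half, but only the Laplacian also shrinks. We do
not compare raw RMS vertex displacement between the two: Laplacian
displacement is dominated by the shrink term that Taubin exists to cancel,
so displacement equality is the wrong invariant.

Smoothing never changes vertex count, face count or topology; boundary
vertices (present only on open meshes) are frozen.

`decimate_mesh()` is quadric-error edge collapse with three guards: the
manifold link condition (a collapse must not create non-manifold edges),
a normal-flip test on surviving faces, and an exact cumulative
enclosed-volume budget (`volume_tol`, default 2% — the volume change of
each candidate collapse is computed in closed form from the affected
triangles). The budget is what makes the operator honest on coarse meshes:
a 12-face box has no collapse that preserves its shape, so it comes back
unchanged with a warning, while a dense icosphere halves its face count
with 0.5% volume error. Collapse positions are chosen among midpoint and
endpoints by quadric cost; the optimal-point linear solve was skipped as
its conditioning pathologies outweigh its benefit at these mesh sizes.

Profile smoothing levels follow the 0/none, 1/low, 2/high convention.
Level iteration counts are profile configuration, not constants; the
shipped presets (e.g. 10/50 Taubin iterations, 5/15 Laplacian) were chosen
once as representative low/high settings.

## Global comparison metrics

Boolean volumes are computed by voxelizing each mesh on a common isotropic
grid (default pitch 0.2 mm standalone, 0.4 mm in the scaled-down study) and
counting voxel centers inside the surface by ray parity. One ray per (x, y)
column classifies a whole column; query coordinates carry a fixed
sub-micron jitter so rays never hit triangle edges exactly, an error shell
orders of magnitude below any pitch. Voxelization was preferred over exact
mesh booleans for robustness: near-degenerate triangle constellations that
break constructive-solid-geometry kernels merely misclassify a
measure-zero set of centers here, and the pitch-convergence property
(agreement at pitch h vs h/2 within 1%) is part of the test suite.

Two overlap normalizations are provided because the printed form of the
agreement/disagreement equations is not pinned down by their textual
description: the symmetric, union-normalized (Jaccard-style) variant —
agreement + disagreement = 100 exactly — is the default; the
reference-normalized `relative_to_a` variant fills asymmetric pairwise
matrices. Every report records which variant produced it. Percent tables
are rounded to whole percents on disk, with full precision kept in the
JSON manifest.

Deviation fields sample surface A (all vertices plus area-uniform extra
samples at a stated density) and take, per sample, the exact
point-to-triangle distance to B via a uniform spatial grid over B's
triangles — not vertex-to-vertex distance, which overestimates; the test
suite asserts the dominance relation. Sign is negative inside B, so
positive deviation means A lies outside B. Hausdorff summaries are
sampling-based estimates: they converge from below, and the triangle
inequality holds only within sampling tolerance, which is how the property
test states it.

No registration is performed anywhere: all models in one run derive from
one volume and share a world frame. Multi-scan registration is out of
scope.

## Local metrics

`slice_mesh()` places `n` parallel datum planes at fractions i/(n+1) of the
mesh extent along the axis — end caps excluded, because planes tangent to a
vertex produce degenerate contours. Triangle–plane intersection segments
are chained into closed loops; loops are classified outer/hole by
containment nesting depth (holes subtract area and weight the centroid
negatively), so a multi-lobed or annular section is handled without
orientation bookkeeping from the chaining order. Exact vertex-on-plane
contacts are nudged off the plane by a relative epsilon; a plane that only
touches a vertex yields an empty slice, flagged rather than thrown.

`contour_centroid_extents()` reads the "X and Y distance to the edges"
measurement as centroid-to-contour ray distances along ±u and ±v; since
that convention is not universal, full widths (ext₊ + ext₋) are also
reported. `nerve_path_compare()` computes, per slice, each model's distance
to the mean centroid over models — with two models those distances are
equal by symmetry, so meaningful spread statistics need three or more
models, as in the four-profile default set.

## Statistics

`one_way_anova()` computes the classical fixed-effects decomposition
explicitly (the object carries SS, df, MS, F, p), with p from the F
distribution; `tukey_kramer()` computes all-pairs studentized-range
statistics in the Kramer form valid for unequal group sizes, compares them
against `q_critical(alpha, k, df)` (the upper-α studentized range quantile,
via R's `qtukey`; q(0.05; 6, 39) = 4.237), and reports the corresponding
p-values alongside the fixed-α decision. The test suite cross-checks the
decomposition against a from-scratch oracle, the F = t² identity at k = 2,
and `TukeyHSD`.

In the study design, each profile contributes its three smoothing-level
values as observations, mirroring the "average over smoothing levels per
program" analysis: smoothing-level variation is the within-group noise
against which the between-workflow effect is judged. No multiplicity
correction is applied across ROIs or metric families — Tukey already
controls the family-wise rate within each measurement family, and
correcting across families would change the question being asked.
Reported CSV numbers are formatted at 6 significant digits so reruns are
byte-identical.

## The scaled-down study and problem sizes

`run_study()` executes phantom → degrade → segment (per profile and ROI) →
mesh → smooth (levels 0/1/2) → metrics → statistics → reports, aborting
with the stage name on failure and retaining partial outputs. The default
configuration uses a 0.5 mm isotropic phantom (≈10⁶ voxels), two to four
workflow profiles, overlap pitch 0.4 mm and deviation sampling at
0.25/mm² — sizes chosen so a complete study runs in about two minutes on
one CPU while every metric stays in its convergent regime. At these
settings the qualitative study result reproduces: smoothing levels within a
profile move the mandible model far less (≈3% pairwise disagreement) than
switching segmentation workflow does (≈21%), and the workflow effect on
volume is highly significant while within-profile smoothing differences are
not.

## Known limitations

* The phantom's HU values, geometry and noise model are stylized; absolute
  disagreement percentages and Hausdorff magnitudes depend on them and
  should not be read as predictions for clinical scans.
* Surface area of rasterized masks carries the tessellation bias discussed
  above.
* Nerve masks at default spacing are only 2–4 voxels across, so nerve
  volumes are heavily quantized; the nerve analysis is about path
  centroids, which are far more stable than volumes at that scale.
* STL I/O stores float32; exact round-trips hold only for
  float32-representable coordinates, and ASCII output is capped at 9
  significant digits.
* No DICOM parsing, no scanner physics, no mesh repair beyond
  duplicate-vertex merging and degenerate-face removal, no multi-modality
  registration, and no emulation of any specific commercial program's
  proprietary algorithms — workflows are generic parameterized stand-ins.
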