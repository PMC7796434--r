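---
title: "Standardized 3D knee BMD mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized 3D knee BMD mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemap)
```

## The problem

Volumetric bone mineral density (BMD) from quantitative CT varies spatially
within the distal femur and proximal tibia, and knees differ in size, shape
and pose in the scanner. To compare BMD across knees (or within a knee over
time) every measurement must be expressed at anatomically corresponding
locations. `kneemap` does this by registering each segmented bone surface
onto a fixed reference bone, carrying the calibrated bone-interior voxels
through the same transformation, and averaging them on the reference bone's
fixed grid of isotropic cells. The result is a standardized BMD map: cell
`(i, j, k)` means the same anatomical location in every knee.

## Calibration

A solid calcium-hydroxyapatite phantom scanned with the knee provides rods of
known equivalent density. `fit_calibration()` fits the ordinary
least-squares line

\[ \mathrm{BMD}\ (\mathrm{mg/cc}) = a \cdot \mathrm{HU} + b \]

to the rod ROI means and `apply_calibration()` maps every voxel through it.
A two-parameter line is the standard model for solid multi-rod phantoms; rod
ROI placement is accepted as input (`phantom_sample`) rather than detected
automatically. The fit reports \(R^2\) so a mis-placed ROI is visible
immediately.

## Phase 1: surface registration

All geometry is in millimetres in a right-handed patient frame; left knees
are mirrored across the sagittal plane on load so registration always runs in
a right-knee convention (the mirroring is a package convention — side handling
is not dictated by the method itself).

**Femur.** The subchondral surfaces of the two condyles lie approximately on
a common cylinder whose axis runs medial to lateral.

1. *Step 1a* — `fit_cylinder()` fits a cylinder to the subchondral patch of
   the moving and the reference femur by orthogonal-distance least squares
   (for a fixed axis the optimal radius is the mean point-to-axis distance,
   so the optimizer runs over the four axis degrees of freedom, initialized
   from the patch's principal directions). The moving femur is then rotated
   and translated so its cylinder axis is colinear with the reference axis
   and the projections of the manually identified trochlear notches onto the
   common axis coincide.
2. *Step 1b* — the moving femur is scaled radially about the axis so the two
   cylinder radii coincide, and each condylar region (notch to medial /
   lateral epicondyle) is scaled separately along the axis so the condylar
   extents match. The axial map is piecewise linear and continuous at the
   notch projection; a blended alternative was considered and rejected
   because the piecewise-linear map is exactly invertible per region and the
   continuity constraint already removes the only seam.
3. *Step 1c* — the residual rotation about the common axis is found by
   minimizing the mean squared point-to-surface distance from the moving
   subchondral vertices to the reference subchondral patch: a coarse grid
   search over the full circle (`rotation_search_resolution`, default 1°)
   followed by golden-section refinement, ties broken toward the smallest
   absolute angle.

**Tibia.** The plateau (medial + lateral subchondral areas) drives a
closed-form similarity transform from correspondence-free patch descriptors:
centroids give the translation, RMS spread about the centroid gives the
isotropic scale, and principal axes give the rotation, with eigenvector signs
fixed by third moments (skewness) along each axis so that the rotation is
unambiguous. A second step scales the bone along its longitudinal axis so the
proximal-segment extents match, anchored at the subchondral centroid so the
plateau does not move. The exact distance criterion used by earlier plateau
alignment work is not published in detail, so conformance here is defined by
the post-condition: for inputs related by an exact similarity, the transform
is recovered (the package tests verify 0.5° / 1% / 0.1 mm on noise-free
pairs, and the recovery is in fact exact to machine precision).

**Step 3 (both bones).** `nonrigid_icp()` alternates (i) exact
point-to-surface projection of every moving vertex onto the reference
surface with (ii) a thin-plate-spline (TPS) update fitted on a fixed uniform
subsample of control vertices (default 500), with the TPS regularization
decreasing over a schedule (default 100, 10, 1, 0.1, 0.01). An update is
accepted only if the mean surface distance does not increase, which makes the
recorded distance sequence non-increasing by construction; a stiffness level
terminates when the mean per-vertex displacement falls below `icp_tol`
(default 1e-3 mm) or the inner budget (default 10) is exhausted.
Non-convergence is reported, not fatal. The classic stiffness-regularized
nonrigid ICP formulation is not reproduced verbatim; the TPS-update variant
was chosen because the same deformation model then serves phase 2 directly,
and conformance is asserted through post-conditions (self-registration is the
identity; smooth 1.5 mm warps converge below 0.1 mm mean distance).

The TPS uses the 3D kernel \(U(r) = r\) plus an affine term; with zero
regularization it interpolates its control pairs exactly, and as the
regularization grows it tends to the least-squares affine fit. The linear
system is solved with two steps of iterative refinement, and the evaluator
computes point-control distances directly (not via the expanded square) to
avoid cancellation — both choices are needed to meet the 1e-9 mm
interpolation tolerance at realistic coordinate magnitudes.

For phase 2 the whole nonrigid displacement is distilled into a single TPS
fitted on a farthest-point subsample of (post-global position → final
position) vertex pairs (default 1000). How the surface transformation is
represented for voxel propagation is an open design point; a single TPS was
chosen because it is smooth, defined everywhere inside the bone, and cheap to
apply to hundreds of thousands of voxel centres.

## Phase 2: voxel propagation and the cell map

`extract_bone_voxels()` returns exactly the voxel centres strictly inside the
watertight bone mesh (ray-parity test; rays that graze an edge are retried
along a different direction). `warp_points()` pushes them through the
transform chain in order; BMD values are carried unchanged — no intensity
resampling and no Jacobian/density correction, matching the method's
definition of the registered voxels as moved samples whose values are then
averaged. `build_cell_grid()` fills the reference bone's bounding box with
isotropic half-open cubic cells (default 2 mm side) anchored at the
bounding-box minimum corner, so cell counts are deterministic; a cell belongs
to the map support when its centre lies inside the reference surface.
`aggregate_bmd()` takes the arithmetic mean per cell (centre-point binning,
no partial-volume splitting — the simplest faithful reading of "voxels
contained within the cell's boundaries"). Cells containing no voxel are
reported missing, never zero, and the per-cell counts plus the out-of-grid
count always equal the number of registered voxels.

The cell counts of the original study (7000 tibial and 12,000 femoral cells)
are properties of its specific reference bones; with this package they are
outcomes of the chosen reference mesh and cell size, not constraints.

## Reliability and reproducibility

`evaluate_settings()` works on a cells × knees × repeats table per
experimental setting.

- **ICC.** `icc_two_way_random()` computes ICC(2,1) — two-way random
  effects, absolute agreement, single measurement:
  \((MS_R - MS_E) / (MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E))\).
  The two-way random-effects family leaves single-vs-average and
  consistency-vs-agreement open; ICC(2,1) was chosen because single
  measurements are compared and scan/operator differences are absolute
  errors. Cells with zero total variance are flagged degenerate and excluded
  from summaries. Classification: poor < 0.5 ≤ moderate < 0.75 ≤ good
  < 0.9 ≤ excellent; the published class limits leave 0.9 itself unassigned
  and it is assigned to excellent here.
- **RMSSD.** Per-knee sample SD across repeats, then the root mean square
  across knees; \(\mathrm{RMSSD}^2\) is an unbiased estimator of the error
  variance.
- **Setting comparisons.** Two-sided Wilcoxon signed-rank tests over the
  per-cell metric vectors, normal approximation with average ranks for ties,
  zeros dropped, no continuity correction; Bonferroni adjustment
  \(p_{adj} = \min(1, 3p)\) for the three pairwise comparisons; effect size
  \(r = |z|/\sqrt{N}\) with \(N\) the number of non-zero pairs (an r-type
  measure consistent in magnitude with the reported effect sizes). An exact
  mode enumerates the null distribution of the statistic and matches
  exhaustive sign-pattern enumeration.

## The synthetic-data module

Because no public dataset exists for this method, every fixture is generated
in code:

- `make_bone_mesh()` builds idealized, watertight bones: a two-lobed femur
  whose subchondral patch lies *exactly* on a cylinder of known radius
  (ground truth for the cylinder fit), interrupted by a trochlear-notch
  indentation, with notch/epicondyle anchors returned; and a tapered
  elliptical tibia with a slightly dished plateau carrying two asymmetric
  subchondral patches (the asymmetry makes the descriptor-based similarity
  alignment well-posed). Default dimensions (condyle radius 21 mm,
  medio-lateral width 76 mm, plateau 76 × 52 mm, proximal segment 60 mm)
  are adult-knee magnitudes. The shapes are deliberately not statistical
  shape models: the method's geometric assumptions, not anatomy, are under
  test, so passing tests demonstrate correctness of the algorithms under
  those assumptions, not segmentation robustness on real knees.
- `random_deformation()` produces smooth, invertible warps (Gaussian
  displacement bumps with amplitude/width ≤ 0.5, composed with a similarity),
  with the inverse computed by fixed-point iteration to < 1e-3 mm.
- `make_ct()` rasterizes a BMD field inside the bone into HU through a known
  calibration line, renders constant-density phantom rods beside the bone
  and measures rod ROI samples from the rendered volume. Noise is i.i.d.
  Gaussian in HU; beam hardening and scatter are not simulated.
- `make_repeated_dataset()` draws per-cell repeated measures with explicit
  variance components (`value = cell mean + knee effect + error`), so the
  ground-truth ICC \(\sigma_b^2 / (\sigma_b^2 + \sigma_e^2)\) is known. The
  default design (10 knees × 2 repeats, three settings) mirrors the scale at
  which the method was originally evaluated; residual SDs of 4, 7 and 10
  mg/cc span the reproducibility range reported for such data.

All generators are pure functions of their specification and seed.

## Numerical choices and problem sizes

- Mesh geometry kernels (ray-parity interior test, exact closest point on a
  triangle mesh) are compiled (Rcpp); the interior test casts the first ray
  along +z with a per-triangle bounding-box reject and falls back to generic
  directions when a hit grazes an edge.
- The cylinder fit rejects coplanar point sets (no finite cylinder); the TPS
  rejects duplicated or coplanar control points (singular system).
- Tests and the reproduction script run the full pipeline at 1 mm voxel
  spacing on bones of ~1700 vertices with 2 mm cells (≈ 11,000 femoral
  interior cells) and the reliability study at 2000 cells × 10 knees × 2
  repeats; these sizes were chosen so the whole suite completes in minutes
  while keeping every quantity at realistic magnitude.

## Known limitations

- Anchors (trochlear notch, epicondyles, longitudinal axis) are inputs;
  there is no automatic landmark detection.
- Segmentation is out of scope: meshes and masks are inputs, and the areas
  of lower reliability that segmentation variability produces in practice
  (epicondyles, notch rim) are not emulated by the synthetic bones.
- No DICOM series assembly, no phantomless calibration, no beam-hardening
  correction, no partial-volume handling at the bone boundary.
- The nonrigid step assumes the global alignment has already removed pose
  and size differences; it is a local matcher, not a general registration.
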