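# kneemap

Standardized three-dimensional bone mineral density (BMD) mapping of the knee
from quantitative CT.

Spatial BMD patterns in the distal femur and proximal tibia matter in
osteoarthritis, fractures, arthroplasty and osteoporosis research, but knees
differ in size, shape and pose, so voxel values from different scans cannot be
compared directly. `kneemap` establishes an anatomical correspondence by
registering each segmented bone surface onto a reference bone and carrying the
calibrated BMD voxels through the same transformation onto the reference
bone's fixed grid of isotropic cells. Cell *(i, j, k)* of the resulting map
then refers to the same anatomical location in every knee, enabling
cross-sectional and longitudinal comparisons at cell resolution. It is
intended for researchers in musculoskeletal imaging and computational anatomy
working with knee QCT and segmented bone meshes.

## Method

1. **Calibration** — ordinary least squares on calibration-phantom rod
   samples: `BMD (mg/cc) = a·HU + b`.
2. **Phase 1, surface registration** (moving bone → reference bone)
   - *Femur*: a cylinder is fitted to the subchondral condylar surface by
     orthogonal-distance least squares; the moving femur is aligned so the
     cylinder axes are colinear and the trochlear-notch projections coincide
     (step 1a), scaled radially to match cylinder radii and per-condyle along
     the axis to match notch-to-epicondyle extents (step 1b), then rotated
     about the axis to minimize the subchondral surface distance (step 1c).
   - *Tibia*: a closed-form similarity transform aligns the plateau
     (subchondral) areas via moment descriptors, followed by a longitudinal
     scaling anchored at the plateau.
   - *Both*: nonrigid ICP — alternating exact point-to-surface projection
     with thin-plate-spline (TPS, kernel `U(r) = r`) updates under a
     decreasing stiffness schedule — locally matches the surfaces.
3. **Phase 2, voxel propagation** — the voxel centres strictly inside the
   bone are pushed through the transform chain (values carried unchanged) and
   averaged per 2 mm half-open cell of the reference grid; empty cells are
   missing, not zero.
4. **Evaluation** — per-cell reliability ICC(2,1)
   `(MS_R − MS_E)/(MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))`, reproducibility
   `RMSSD = sqrt(mean_i SD_i²)` (mg/cc), and pairwise setting comparisons by
   Wilcoxon signed-rank tests with Bonferroni correction and effect size
   `r = |z|/√N`.

A synthetic-data module generates watertight bone-like labeled meshes with
analytic ground truth, rasterized CT volumes with phantom rods, smooth
invertible deformations, and repeated-measures tables with known variance
components, so the whole pipeline is testable without patient data.

## Worked example

```r
library(kneemap)

# reference and moving synthetic femurs (moving = smoothly deformed copy)
ref <- make_bone_mesh(synthetic_bone_spec("femur"))
def <- random_deformation(domain_radius = 35, amplitude = 1.5, width = 25,
  similarity = similarity_transform(translation = c(6, -4, 2), scale = 1.08),
  seed = 2)
mov <- deform_bone(ref, def)

# synthetic CT of the moving knee with calibration-phantom rods
ct <- make_ct(mov$mesh, function(p) 150 + 1.2 * p[, 1], spacing = c(1, 1, 1),
              noise_sd = 2, seed = 2)
model <- fit_calibration(ct$samples)
print(model)
#> calibration_model: BMD = 0.799981 * HU + -4.99915 mg/cc (R^2 = 1.00000, n = 4)

# register the moving femur onto the reference
warp <- register_bone(mov$mesh, ref$mesh,
                      anchors = list(moving = mov$anchors, reference = ref$anchors))
attr(warp, "mean_distance")
#> final mean surface distance: 0.007 mm

# propagate calibrated voxels and build the standardized map
cloud <- extract_bone_voxels(apply_calibration(ct$volume, model), mov$mesh)
grid  <- build_cell_grid(ref$mesh, cell_size = 2)
map   <- aggregate_bmd(warp_points(cloud, warp), grid)
print(map)
#> bmd_map: 11118 occupied cells (of 11118 interior), 109806 voxels binned, 3165 out of grid
```

The ground-truth calibration line of the simulated scanner was
`0.8·HU − 5`, so the fitted slope/intercept are recovered to 0.002%; the
registration residual (0.007 mm mean surface distance) is far below the voxel
size; and the 11,118 interior 2 mm cells show every interior cell received
voxels, with 3,165 voxels landing outside the map support (near the surface)
excluded rather than misassigned.

Reliability evaluation at the design scale of a repeated-scan study
(10 knees × 2 repeats, between-knee SD 30 mg/cc, residual SD 4 vs 10 mg/cc):

```r
ds <- make_repeated_dataset(n_cells = 2000, n_knees = 10, n_repeats = 2,
  sigma_between = 30, per_setting_sigmas = c(intra = 4, inter = 10), seed = 2)
ev <- evaluate_settings(ds$settings)
ev$summary
#>   setting icc_median icc_q1 icc_q3 rmssd_median rmssd_q1 rmssd_q3 pct_excellent
#> 1   intra      0.982  0.973  0.989         3.86     3.26     4.43          99.4
#> 2   inter      0.904  0.847  0.936         9.59     8.11    11.09          51.9
ev$comparisons[, c("pair", "metric", "z", "p_adjusted", "effect_size")]
#>             pair metric     z p_adjusted effect_size
#> 1 intra vs inter    icc  38.7          0       0.866
#> 2 intra vs inter  rmssd -38.7          0       0.866
```

The median RMSSD tracks the injected residual SD (3.86 vs 4; 9.59 vs 10,
RMSSD at 2 repeats is noisy per cell), the median ICC tracks the
variance-component truth (0.9 and 0.983), and the lower-noise setting is
detected as significantly more reliable and reproducible.

A command-line interface wrapping the same functions is installed at
`inst/exec/kneemap` (`kneemap calibrate|register|map|evaluate|simulate`).

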