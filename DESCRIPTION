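Package: kneemap
Title: Standardized Three-Dimensional Bone Mineral Density Mapping of the Knee
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to express quantitative computed tomography (QCT) bone
    mineral density (BMD) of the distal femur and proximal tibia on a common
    anatomical reference. Provides phantom-based HU-to-BMD calibration, a
    two-phase registration pipeline (cylinder-based global alignment of the
    femoral condyles and descriptor-based alignment of the tibial plateau,
    followed by nonrigid iterative-closest-point matching with thin-plate-spline
    deformation), propagation of the surface warp to bone-interior voxels,
    aggregation onto a fixed isotropic cell grid, and a reliability and
    reproducibility evaluation framework (per-cell intraclass correlation,
    root-mean-square precision error, and paired setting comparisons). A
    synthetic-data module generates labeled bone-like meshes, rasterized CT
    volumes with calibration rods, and repeated-measures BMD tables with known
    variance components, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
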