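test_that("bone generators are deterministic and watertight", {
  for (bone in c("femur", "tibia")) {
    spec <- synthetic_bone_spec(bone)
    a <- make_bone_mesh(spec)
    b <- make_bone_mesh(spec)
    expect_identical(a$mesh$vertices, b$mesh$vertices)
    expect_identical(a$mesh$faces, b$mesh$faces)
    expect_true(is_watertight(a$mesh))
    expect_gt(sum(a$mesh$subchondral_mask), 50)
  }
  noisy <- synthetic_bone_spec("femur", noise_sd = 0.1, seed = 9)
  expect_identical(make_bone_mesh(noisy)$mesh$vertices,
                   make_bone_mesh(noisy)$mesh$vertices)
  expect_false(identical(
    make_bone_mesh(noisy)$mesh$vertices,
    make_bone_mesh(synthetic_bone_spec("femur", noise_sd = 0.1, seed = 10))$mesh$vertices))
})

test_that("invalid bone dimensions are rejected", {
  expect_error(synthetic_bone_spec("tibia", shaft_length = -5), "positive")
  expect_error(synthetic_bone_spec("femur", condyle_radius = 0), "positive")
  expect_error(synthetic_bone_spec("femur",
                                   resolution = list(n_theta = 4L, n_axis = 3L)),
               "resolution")
})

test_that("synthetic deformations are invertible on the mesh domain", {
  def <- random_deformation(domain_radius = 30, n_bumps = 5, amplitude = 2,
                            width = 25,
                            similarity = similarity_transform(
                              kneemap:::rotation_about_axis(c(1, 0, 1), 0.2),
                              c(3, 1, -2), 1.1),
                            seed = 60)
  pts <- make_bone_mesh(small_femur_spec())$mesh$vertices
  fwd <- apply_deformation(def, pts)
  back <- invert_deformation(def, fwd)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 1e-3)
  expect_error(deformation_spec(matrix(0, 1, 3), matrix(c(20, 0, 0), 1, 3), 5),
               "diffeomorphic")
})

test_that("make_ct renders identity-calibration interiors exactly", {
  fem <- make_bone_mesh(small_femur_spec())$mesh
  ct <- make_ct(fem, function(p) rep(100, nrow(p)), spacing = c(2, 2, 2),
                calibration_truth = list(slope = 1, intercept = 0),
                noise_sd = 0)
  expect_true(all(ct$volume$voxels[ct$inside] == 100))
  # background corner voxel sits at the soft-tissue value
  expect_equal(ct$volume$voxels[1, 1, 1], -70)
  expect_error(make_ct(fem, function(p) rep(100, nrow(p)),
                       spacing = c(500, 500, 500)), "spacing")
})

test_that("repeated-measures generator hits its variance components", {
  ds0 <- make_repeated_dataset(200, 10, 2, sigma_between = 30, sigma_error = 0,
                               seed = 61)
  v <- ds0$settings[[1]]$values
  expect_equal(v[, , 1], v[, , 2])
  ev0 <- evaluate_settings(ds0$settings)
  expect_true(all(ev0$per_cell$rmssd_setting1 == 0))

  ds <- make_repeated_dataset(2000, 10, 2, sigma_between = 30, sigma_error = 10,
                              seed = 62)
  expect_equal(ds$truth_icc[[1]], 0.9)
  ev <- evaluate_settings(ds$settings)
  expect_lt(abs(ev$summary$icc_median - 0.9), 0.05)
  expect_lt(abs(ev$summary$rmssd_median - 10) / 10, 0.15)

  again <- make_repeated_dataset(2000, 10, 2, sigma_between = 30,
                                 sigma_error = 10, seed = 62)
  expect_identical(ds$settings[[1]]$values, again$settings[[1]]$values)
  expect_error(make_repeated_dataset(10, n_repeats = 1), "n_repeats")
})
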