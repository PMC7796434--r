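test_that("exact rod sets give the exact calibration line", {
  m1 <- fit_calibration(list(phantom_sample(0, 0, 10),
                             phantom_sample(100, 100, 10)))
  expect_equal(m1$slope, 1, tolerance = 1e-12)
  expect_equal(m1$intercept, 0, tolerance = 1e-12)
  expect_equal(m1$r_squared, 1, tolerance = 1e-12)

  m2 <- fit_calibration(list(phantom_sample(-50, 0, 5), phantom_sample(0, 50, 5),
                             phantom_sample(50, 100, 5)))
  expect_equal(m2$slope, 1, tolerance = 1e-12)
  expect_equal(m2$intercept, 50, tolerance = 1e-12)
})

test_that("noisy fits match the closed-form normal-equations solution", {
  set.seed(10)
  for (rep in 1:5) {
    hu <- c(-30, 10, 60, 130, 250) + rnorm(5, 0, 3)
    dens <- 0.8 * hu - 5 + rnorm(5, 0, 4)
    m <- fit_calibration(Map(phantom_sample, hu, pmax(dens, 0), 20))
    x <- cbind(1, hu)
    beta <- solve(t(x) %*% x, t(x) %*% pmax(dens, 0))
    expect_equal(m$intercept, beta[1], tolerance = 1e-9)
    expect_equal(m$slope, beta[2], tolerance = 1e-9)
  }
})

test_that("degenerate rod sets are rejected", {
  expect_error(fit_calibration(list(phantom_sample(50, 100, 5))), ">= 2")
  expect_error(fit_calibration(list(phantom_sample(50, 100, 5),
                                    phantom_sample(50, 200, 5))), "distinct")
})

test_that("apply_calibration is the affine voxel map, geometry untouched", {
  vol <- ct_volume(array(100, c(4, 4, 4)), c(1, 1, 1), origin = c(5, 5, 5))
  ident <- fit_calibration(list(phantom_sample(0, 0, 1), phantom_sample(1, 1, 1)))
  out <- apply_calibration(vol, ident)
  expect_equal(out$voxels, vol$voxels)
  m <- structure(list(slope = 0.8, intercept = -5, r_squared = 1,
                      n_samples = 2L), class = "calibration_model")
  out2 <- apply_calibration(vol, m)
  expect_true(all(out2$voxels == 75))
  expect_equal(out2$spacing, vol$spacing)
  expect_equal(out2$origin, vol$origin)
  expect_identical(out2$units, "mg/cc")
})

test_that("fitting rods of a synthetic phantom volume recovers the truth line", {
  fem <- make_bone_mesh(small_femur_spec())$mesh
  truth <- list(slope = 0.75, intercept = -8)
  ct <- make_ct(fem, function(p) rep(200, nrow(p)), spacing = c(1.5, 1.5, 1.5),
                calibration_truth = truth, noise_sd = 5, seed = 3)
  model <- fit_calibration(ct$samples)
  expect_lt(abs(model$slope - truth$slope) / truth$slope, 0.01)
  # noiseless: the calibrated volume reproduces the ground-truth BMD field
  ct0 <- make_ct(fem, function(p) 100 + p[, 3], spacing = c(1.5, 1.5, 1.5),
                 calibration_truth = truth, noise_sd = 0)
  cal0 <- apply_calibration(ct0$volume, fit_calibration(ct0$samples))
  inside <- ct0$inside
  expect_lt(max(abs(cal0$voxels[inside] - ct0$truth_bmd$voxels[inside])), 1e-6)
})

test_that("phantom sample CSV and model YAML interfaces round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(rod_id = 1:3, mean_hu = c(0, 100, 200),
                       known_density_mgcc = c(0, 80, 160), n_voxels = 50),
            path, row.names = FALSE)
  samples <- read_phantom_samples(path)
  model <- fit_calibration(samples)
  expect_equal(model$slope, 0.8, tolerance = 1e-12)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(model, ypath)
  back <- read_calibration(ypath)
  expect_equal(back$slope, model$slope)
  expect_equal(back$intercept, model$intercept)
})
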