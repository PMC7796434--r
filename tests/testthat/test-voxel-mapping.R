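test_that("extract_bone_voxels equals a brute-force interior test on a cube", {
  cube <- cube_mesh(20)
  vol <- ct_volume(array(runif(30^3, 50, 300), c(30, 30, 30)),
                   spacing = c(1, 1, 1), origin = c(-4.5, -4.5, -4.5),
                   units = "mg/cc")
  cloud <- extract_bone_voxels(vol, cube)
  centers <- voxel_centers(vol)
  truth <- centers[, 1] > 0 & centers[, 1] < 20 &
    centers[, 2] > 0 & centers[, 2] < 20 &
    centers[, 3] > 0 & centers[, 3] < 20
  expect_equal(nrow(cloud$points), sum(truth))
  expect_equal(cloud$points, centers[truth, , drop = FALSE])
  expect_equal(cloud$values, as.vector(vol$voxels)[truth])
})

test_that("a mesh outside the volume yields an empty cloud; open meshes error", {
  cube <- cube_mesh(5)
  vol <- ct_volume(array(100, c(5, 5, 5)), c(1, 1, 1), origin = c(100, 100, 100),
                   units = "mg/cc")
  cloud <- extract_bone_voxels(vol, cube)
  expect_equal(nrow(cloud$points), 0L)
  open <- cube
  open$faces <- open$faces[-1, , drop = FALSE]
  expect_error(extract_bone_voxels(vol, open), "watertight")
})

test_that("warp_points matches independent sequential application", {
  set.seed(40)
  pts <- matrix(runif(300, -10, 10), ncol = 3)
  cloud <- bmd_point_cloud(pts, runif(100, 50, 400))
  sim <- similarity_transform(kneemap:::rotation_about_axis(c(1, 2, 3), 0.4),
                              c(2, -1, 5), 1.07)
  src <- matrix(runif(36, -12, 12), ncol = 3)
  tps <- fit_tps(src, src + matrix(rnorm(36, sd = 0.8), ncol = 3), 0)
  out <- warp_points(cloud, composite_warp(sim, tps))
  manual <- apply_transform(tps, apply_transform(sim, pts))
  expect_lt(max(abs(out$points - manual)), 1e-9)
  expect_identical(out$values, cloud$values)
})

test_that("cell grids have analytic counts on a cube and match brute force on a sphere", {
  cube <- cube_mesh(20)
  grid <- build_cell_grid(cube, 2)
  expect_identical(grid$dims, c(10L, 10L, 10L))
  expect_equal(sum(grid$interior_mask), 1000L)
  expect_error(build_cell_grid(cube, 0), "positive")

  sph <- sphere_mesh(10, n_theta = 36, n_phi = 18)
  gs <- build_cell_grid(sph, 2)
  tab <- kneemap:::interior_cell_table(gs)
  centers <- as.matrix(tab[, c("x", "y", "z")])
  expect_true(all(points_in_mesh(centers, sph)))
  expect_equal(sum(gs$interior_mask), sum(points_in_mesh(
    as.matrix(expand.grid(
      gs$origin[1] + (seq_len(gs$dims[1]) - 0.5) * 2,
      gs$origin[2] + (seq_len(gs$dims[2]) - 0.5) * 2,
      gs$origin[3] + (seq_len(gs$dims[3]) - 0.5) * 2)), sph)))
})

test_that("aggregation averages per cell and matches a binning oracle", {
  cube <- cube_mesh(20)
  grid <- build_cell_grid(cube, 2)
  # constant field
  set.seed(41)
  pts <- matrix(runif(3000, 0.1, 19.9), ncol = 3)
  mapc <- aggregate_bmd(bmd_point_cloud(pts, rep(100, 1000)), grid)
  expect_true(all(mapc$mean[mapc$count > 0] == 100))
  # mean of two in one cell
  two <- aggregate_bmd(bmd_point_cloud(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                                       c(80, 120)), grid)
  expect_equal(two$mean[1, 1, 1], 100)
  expect_equal(sum(two$count), 2L)
  # random cloud vs brute-force bin-then-average
  vals <- runif(1000, 50, 400)
  map <- aggregate_bmd(bmd_point_cloud(pts, vals), grid)
  idx <- floor(pts / 2) + 1
  for (probe in sample(which(map$count > 0), 25)) {
    ai <- arrayInd(probe, grid$dims)
    in_cell <- idx[, 1] == ai[1] & idx[, 2] == ai[2] & idx[, 3] == ai[3]
    expect_equal(map$mean[probe], mean(vals[in_cell]), tolerance = 1e-9)
    expect_equal(map$count[probe], sum(in_cell))
  }
})

test_that("voxel conservation holds and empty cells are missing, not zero", {
  cube <- cube_mesh(20)
  grid <- build_cell_grid(cube, 2)
  set.seed(42)
  pts <- matrix(runif(1500, -5, 25), ncol = 3)   # some points out of grid
  cloud <- bmd_point_cloud(pts, runif(500, 50, 400))
  map <- aggregate_bmd(cloud, grid)
  expect_identical(sum(map$count) + map$out_of_grid, map$total_points)
  expect_true(all(is.na(map$mean[map$count == 0])))
})

test_that("self-mapping with the identity warp reproduces direct aggregation", {
  fb <- make_bone_mesh(small_femur_spec())
  vol <- make_ct(fb$mesh, function(p) 150 + p[, 1], spacing = c(2, 2, 2))
  cal <- apply_calibration(vol$volume, fit_calibration(vol$samples))
  cloud <- extract_bone_voxels(cal, fb$mesh)
  grid <- build_cell_grid(fb$mesh, 2)
  direct <- aggregate_bmd(cloud, grid)
  identity_chain <- composite_warp(similarity_transform())
  warped <- aggregate_bmd(warp_points(cloud, identity_chain), grid)
  expect_identical(warped$mean, direct$mean)
  expect_identical(warped$count, direct$count)
})
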