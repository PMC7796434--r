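test_that("TPS with zero regularization interpolates control points exactly", {
  set.seed(20)
  src <- matrix(runif(3 * 30, -20, 20), ncol = 3)
  tgt <- src + matrix(rnorm(3 * 30, sd = 2), ncol = 3)
  warp <- fit_tps(src, tgt, regularization = 0)
  expect_lt(max(abs(apply_transform(warp, src) - tgt)), 1e-9)
})

test_that("TPS on identical pairs is the identity everywhere", {
  set.seed(21)
  src <- matrix(runif(15, -10, 10), ncol = 3)
  warp <- fit_tps(src, src, 0)
  expect_lt(max(abs(warp$kernel_weights)), 1e-10)
  expect_lt(max(abs(warp$affine_part - cbind(0, diag(3)))), 1e-10)
  held_out <- matrix(runif(300, -15, 15), ncol = 3)
  expect_lt(max(abs(apply_transform(warp, held_out) - held_out)), 1e-9)
})

test_that("affine-consistent targets yield a pure affine with no bending", {
  set.seed(22)
  src <- matrix(runif(3 * 25, -20, 20), ncol = 3)
  A <- matrix(c(1.05, 0.1, -0.02, -0.08, 0.95, 0.03, 0.01, -0.05, 1.1), 3, 3)
  b <- c(4, -2, 7)
  tgt <- src %*% t(A) + matrix(b, nrow(src), 3, byrow = TRUE)
  warp <- fit_tps(src, tgt, 0)
  expect_lt(warp$bending_energy, 1e-12)
  held_out <- matrix(runif(300, -25, 25), ncol = 3)
  direct <- held_out %*% t(A) + matrix(b, 100, 3, byrow = TRUE)
  expect_lt(max(abs(apply_transform(warp, held_out) - direct)), 1e-9)
})

test_that("TPS tends to the least-squares affine as regularization grows", {
  set.seed(23)
  src <- matrix(runif(3 * 40, -20, 20), ncol = 3)
  tgt <- src + matrix(rnorm(3 * 40, sd = 3), ncol = 3)
  warp <- fit_tps(src, tgt, regularization = 1e8)
  X <- cbind(1, src)
  beta <- solve(crossprod(X), crossprod(X, tgt))    # LS affine oracle
  pts <- matrix(runif(60, -20, 20), ncol = 3)
  expect_lt(max(abs(apply_transform(warp, pts) - cbind(1, pts) %*% beta)), 1e-4)
})

test_that("degenerate TPS control sets are rejected", {
  src <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(0, 1, 1))
  expect_error(fit_tps(src, src, 0), "duplicate")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(fit_tps(flat, flat, 0), "coplanar")
  expect_error(fit_tps(diag(3), diag(3), 0), ">= 4")
})

test_that("similarity, axial rotation and region scaling behave geometrically", {
  R <- kneemap:::rotation_about_axis(c(0, 0, 1), pi / 6)
  tr <- similarity_transform(R, c(1, 2, 3), 2)
  p <- matrix(c(1, 0, 0), 1)
  expect_equal(as.numeric(apply_transform(tr, p)),
               2 * as.numeric(R %*% c(1, 0, 0)) + c(1, 2, 3), tolerance = 1e-12)
  inv <- kneemap:::invert_similarity(tr)
  pts <- matrix(runif(30), ncol = 3)
  expect_lt(max(abs(apply_transform(inv, apply_transform(tr, pts)) - pts)), 1e-12)

  rot <- axial_rotation(c(0, 0, 0), c(1, 0, 0), 90)
  expect_equal(as.numeric(apply_transform(rot, matrix(c(0, 1, 0), 1))),
               c(0, 0, 1), tolerance = 1e-12)

  rs <- region_scaling(c(0, 0, 0), c(1, 0, 0), radial_scale = 0.5,
                       medial_axial_scale = 2, lateral_axial_scale = 3,
                       boundary_coordinate = 1)
  # continuity at the boundary
  eps <- 1e-9
  left <- apply_transform(rs, matrix(c(1 - eps, 4, 0), 1))
  right <- apply_transform(rs, matrix(c(1 + eps, 4, 0), 1))
  expect_lt(max(abs(left - right)), 1e-6)
  # medial side (axial < boundary) scales by 2 about the boundary
  expect_equal(as.numeric(apply_transform(rs, matrix(c(0, 4, 0), 1))),
               c(1 + 2 * (0 - 1), 2, 0), tolerance = 1e-12)
  expect_error(region_scaling(c(0, 0, 0), c(1, 0, 0), -1, 1, 1, 0), "positive")
})

test_that("composite warps apply the chain in list order", {
  set.seed(24)
  tr1 <- similarity_transform(diag(3), c(3, 0, 0), 1)
  src <- matrix(runif(3 * 12, -10, 10), ncol = 3)
  tr2 <- fit_tps(src, src + matrix(rnorm(36, sd = 1), ncol = 3), 0)
  chain <- composite_warp(tr1, tr2)
  pts <- matrix(runif(150, -8, 8), ncol = 3)
  manual <- apply_transform(tr2, apply_transform(tr1, pts))
  expect_lt(max(abs(apply_transform(chain, pts) - manual)), 1e-9)
  # identity chain and pure translation on a point cloud
  cloud <- bmd_point_cloud(pts, rep(100, nrow(pts)))
  shifted <- warp_points(cloud, composite_warp(tr1))
  expect_equal(shifted$points, sweep(pts, 2, c(3, 0, 0), "+"))
  expect_identical(shifted$values, cloud$values)
})

test_that("composite warps survive serialization at full precision", {
  set.seed(25)
  src <- matrix(runif(3 * 10, -10, 10), ncol = 3)
  chain <- composite_warp(
    similarity_transform(kneemap:::rotation_about_axis(c(0, 1, 0), 0.3),
                         c(1.5, -2, 0.25), 1.1),
    region_scaling(c(0, 0, 0), c(1, 0, 0), 0.9, 1.1, 1.2, 0.5),
    axial_rotation(c(0, 0, 0), c(1, 0, 0), -12.5),
    fit_tps(src, src + matrix(rnorm(30, sd = 0.5), ncol = 3), 0))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_warp(chain, path)
  back <- read_warp(path)
  pts <- matrix(runif(120, -10, 10), ncol = 3)
  expect_lt(max(abs(apply_transform(back, pts) - apply_transform(chain, pts))),
            1e-9)
})
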