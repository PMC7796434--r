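fb <- make_bone_mesh(small_femur_spec())
ref <- fb$mesh

test_that("step 1a inverts a pure translation and aligns axes after rotation", {
  tr <- similarity_transform(diag(3), c(10, -5, 3), 1)
  mov <- ref; mov$vertices <- apply_transform(tr, ref$vertices)
  s1a <- femur_align_step1a(mov, ref, move_anchors(fb$anchors, tr), fb$anchors)
  expect_lt(max(abs(s1a$rotation - diag(3))), 1e-6)
  expect_equal(s1a$translation, c(-10, 5, -3), tolerance = 1e-6)

  R <- kneemap:::rotation_about_axis(c(0, 1, 0), 15 * pi / 180)
  tr2 <- similarity_transform(R, c(2, 1, -4), 1)
  mov2 <- ref; mov2$vertices <- apply_transform(tr2, ref$vertices)
  s <- femur_align_step1a(mov2, ref, move_anchors(fb$anchors, tr2), fb$anchors)
  # post-conditions: axis colinearity and notch-projection coincidence
  fm <- attr(s, "moving_fit"); fr <- attr(s, "reference_fit")
  mapped_dir <- as.numeric(s$rotation %*% fm$axis_dir)
  expect_lt(acos(min(1, abs(sum(mapped_dir * fr$axis_dir)))), 1e-6)
  notch_m <- move_anchors(fb$anchors, tr2)$trochlear_notch
  notch_m_post <- as.numeric(apply_transform(s, matrix(notch_m, 1)))
  proj <- function(p, fit) sum((p - fit$axis_point) * fit$axis_dir)
  expect_lt(abs(proj(notch_m_post, fr) - proj(fb$anchors$trochlear_notch, fr)),
            1e-5)
})

test_that("step 1a requires the trochlear notch", {
  expect_error(
    femur_align_step1a(ref, ref, anchor_set(medial_epicondyle = c(-1, 0, 0),
                                            lateral_epicondyle = c(1, 0, 0)),
                       fb$anchors),
    "trochlear_notch")
})

test_that("step 1b produces the radius and condylar extent ratios", {
  fit_r <- kneemap:::femur_cylinder(ref, fb$anchors)
  fit_m <- fit_r; fit_m$radius <- 25
  fake_r <- fit_r; fake_r$radius <- 20
  anch_m <- fb$anchors
  # moving condyles: medial extent 30, lateral same as reference
  t0 <- sum((fb$anchors$trochlear_notch - fit_r$axis_point) * fit_r$axis_dir)
  anch_m$medial_epicondyle <- fb$anchors$trochlear_notch + (t0 - 30 - t0) * fit_r$axis_dir
  ref_med_ext <- 24
  anch_r <- fb$anchors
  anch_r$medial_epicondyle <- fb$anchors$trochlear_notch - ref_med_ext * fit_r$axis_dir
  s1b <- femur_scale_step1b(ref, ref, fits = list(moving = fit_m, reference = fake_r),
                            anchors = list(moving = anch_m, reference = anch_r))
  expect_equal(s1b$radial_scale, 20 / 25, tolerance = 1e-12)
  expect_equal(s1b$medial_axial_scale, 24 / 30, tolerance = 1e-9)
  expect_equal(s1b$lateral_axial_scale, 1, tolerance = 1e-9)
})

test_that("a uniformly magnified femur is rescaled onto the reference", {
  s <- 1.2
  tr <- similarity_transform(diag(3), c(0, 0, 0), s)
  mov <- ref; mov$vertices <- apply_transform(tr, ref$vertices)
  anch_m <- move_anchors(fb$anchors, tr)
  s1a <- femur_align_step1a(mov, ref, anch_m, fb$anchors)
  mov$vertices <- apply_transform(s1a, mov$vertices)
  anch_m <- move_anchors(anch_m, s1a)
  fit_m <- attr(s1a, "moving_fit"); fit_r <- attr(s1a, "reference_fit")
  fit_m_post <- fit_m
  fit_m_post$axis_dir <- fit_r$axis_dir
  fit_m_post$axis_point <- as.numeric(apply_transform(s1a, matrix(fit_m$axis_point, 1)))
  s1b <- femur_scale_step1b(mov, ref, fits = list(moving = fit_m_post, reference = fit_r),
                            anchors = list(moving = anch_m, reference = fb$anchors))
  expect_equal(s1b$radial_scale, 1 / s, tolerance = 1e-4)
  expect_equal(s1b$medial_axial_scale, 1 / s, tolerance = 1e-4)
  expect_equal(s1b$lateral_axial_scale, 1 / s, tolerance = 1e-4)
  mov$vertices <- apply_transform(s1b, mov$vertices)
  sub <- mov$subchondral_mask
  rms <- sqrt(mean(rowSums((mov$vertices[sub, ] - ref$vertices[sub, ])^2)))
  expect_lt(rms, 0.01)
})

test_that("step 1c recovers a known axial rotation and is 0 at self-alignment", {
  fit_r <- kneemap:::femur_cylinder(ref, fb$anchors)
  s0 <- femur_rotate_step1c(ref, ref, fit_r$axis_point, fit_r$axis_dir)
  expect_lt(abs(s0$angle_deg), 0.05)

  rot_true <- axial_rotation(fit_r$axis_point, fit_r$axis_dir, 10)
  mov <- ref; mov$vertices <- apply_transform(rot_true, ref$vertices)
  s <- femur_rotate_step1c(mov, ref, fit_r$axis_point, fit_r$axis_dir)
  expect_lt(abs(s$angle_deg + 10), 0.05)
})

test_that("step 1c rejects empty subchondral sets", {
  bare <- ref; bare$subchondral_mask[] <- FALSE
  expect_error(femur_rotate_step1c(bare, ref, c(0, 0, 0), c(1, 0, 0)),
               "subchondral")
})
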