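# Fixtures built in code: tiny analytic meshes and low-resolution synthetic
# bones used across tests.

# axis-aligned cube [0, side]^3 as a watertight 12-triangle mesh
cube_mesh <- function(side = 20, bone = "femur") {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f, bone = bone)
}

# UV-sphere of given radius, watertight (polar grid + two apices)
sphere_mesh <- function(radius = 10, n_theta = 24, n_phi = 12) {
  phis <- seq(0, pi, length.out = n_phi + 2)[2:(n_phi + 1)]
  thetas <- seq(-pi, pi - 2 * pi / n_theta, length.out = n_theta)
  verts <- do.call(rbind, lapply(phis, function(ph)
    cbind(radius * sin(ph) * cos(thetas), radius * sin(ph) * sin(thetas),
          radius * cos(ph))))
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- do.call(rbind, lapply(seq_len(n_phi - 1L), function(i) {
    j <- seq_len(n_theta)
    rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
          cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }))
  top <- nrow(verts) + 1L; bot <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, radius), c(0, 0, -radius))
  j <- seq_len(n_theta); jn <- (j %% n_theta) + 1L
  faces <- rbind(faces, cbind(top, j, jn),
                 cbind(bot, idx(n_phi, jn), idx(n_phi, j)))
  surface_mesh(verts, faces, bone = "femur")
}

# regular tetrahedron with one labeled vertex
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  surface_mesh(v, f, subchondral_mask = c(TRUE, FALSE, FALSE, FALSE))
}

# low-resolution bones for fast registration tests
small_femur_spec <- function(...) {
  synthetic_bone_spec("femur", resolution = list(n_theta = 36L, n_axis = 26L), ...)
}
small_tibia_spec <- function(...) {
  synthetic_bone_spec("tibia",
                      resolution = list(n_theta = 36L, n_axis = 16L,
                                        n_radial = 8L), ...)
}

# transform all anchor points of a femur anchor set
move_anchors <- function(anchors, tr) {
  out <- anchors
  for (f in c("trochlear_notch", "medial_epicondyle", "lateral_epicondyle"))
    if (!is.null(out[[f]]))
      out[[f]] <- as.numeric(apply_transform(tr, matrix(out[[f]], 1)))
  out
}

# rotation angle (degrees) of a rotation matrix
rotation_angle_deg <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
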