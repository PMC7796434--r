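# Tibial global alignment: a closed-form similarity transform computed from
# correspondence-free descriptors of the subchondral (plateau) area, followed
# by a scaling along the longitudinal axis anchored at the plateau.

# moment descriptors of a labeled patch: centroid, principal axes with signs
# fixed by third moments, RMS spread
patch_descriptors <- function(points) {
  n <- nrow(points)
  if (n < 4) stop("degenerate patch geometry (fewer than 4 labeled vertices)")
  ctr <- colMeans(points)
  centered <- sweep(points, 2, ctr)
  cov <- crossprod(centered) / n
  eig <- eigen(cov, symmetric = TRUE)
  E <- eig$vectors
  skew <- numeric(3)
  for (k in 1:3) {
    proj <- centered %*% E[, k]
    skew[k] <- mean(proj^3)
    if (skew[k] < 0) {
      E[, k] <- -E[, k]
      skew[k] <- -skew[k]
    }
  }
  if (det(E) < 0) E[, which.min(abs(skew))] <- -E[, which.min(abs(skew))]
  list(centroid = ctr, axes = E, eigenvalues = eig$values,
       rms = sqrt(mean(rowSums(centered^2))))
}

#' Tibia step 1: global similarity alignment on the plateau
#'
#' Computes a translation, rotation and isotropic scaling that aligns the
#' moving tibia's subchondral (medial + lateral plateau) area to the
#' reference's. The transform is closed form, from correspondence-free patch
#' descriptors: centroids give the translation, the RMS spread about the
#' centroid gives the scale, and principal axes (signs fixed by third moments)
#' give the rotation. For inputs related by an exact similarity, the
#' subchondral centroids coincide after alignment.
#'
#' @param moving,reference tibial [surface_mesh()] objects with non-empty
#'   subchondral masks.
#' @return a [similarity_transform()].
#' @export
tibia_align_step1 <- function(moving, reference) {
  stopifnot(moving$bone == "tibia", reference$bone == "tibia")
  if (!any(moving$subchondral_mask)) stop("moving tibia has an empty subchondral mask")
  if (!any(reference$subchondral_mask)) stop("reference tibia has an empty subchondral mask")
  dm <- patch_descriptors(moving$vertices[moving$subchondral_mask, , drop = FALSE])
  dr <- patch_descriptors(reference$vertices[reference$subchondral_mask, , drop = FALSE])
  if (dm$rms < 1e-9) stop("degenerate patch geometry on moving tibia")
  s <- dr$rms / dm$rms
  R <- dr$axes %*% t(dm$axes)
  # guard numerical drift so similarity_transform's orthonormality check passes
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  similarity_transform(R, dr$centroid - s * as.numeric(R %*% dm$centroid), s)
}

#' Tibia step 2: longitudinal scaling anchored at the plateau
#'
#' After step 1, scales the moving tibia along the longitudinal axis so its
#' proximal-segment axial extent matches the reference's. The scaling is
#' anchored at the subchondral surface (the mean axial coordinate of the
#' subchondral vertices), so the plateau does not move.
#'
#' @param moving,reference tibial meshes (moving already moved by step 1).
#' @param longitudinal_axes list with `moving` and `reference` unit 3-vectors;
#'   the reference axis defines the scaling direction in the common frame.
#' @return a [region_scaling()] transform with equal axial scales (pure axial
#'   scaling about the plateau anchor); its `radial_scale` is 1.
#' @export
tibia_scale_step2 <- function(moving, reference, longitudinal_axes) {
  axis_dir <- unit3(longitudinal_axes$reference %||% longitudinal_axes[[1]])
  tm <- moving$vertices %*% axis_dir
  tr <- reference$vertices %*% axis_dir
  extent_m <- max(tm) - min(tm)
  extent_r <- max(tr) - min(tr)
  if (extent_m < 1e-9) stop("zero axial extent on moving tibia")
  s <- extent_r / extent_m
  if (!any(moving$subchondral_mask)) stop("moving tibia has an empty subchondral mask")
  anchor <- colMeans(moving$vertices[moving$subchondral_mask, , drop = FALSE])
  region_scaling(axis_point = anchor, axis_dir = axis_dir,
                 radial_scale = 1,
                 medial_axial_scale = s, lateral_axial_scale = s,
                 boundary_coordinate = 0)
}
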