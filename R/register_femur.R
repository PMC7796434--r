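# Femoral global alignment: the subchondral surfaces of the two condyles lie
# approximately on a cylinder whose axis runs medial to lateral. Step 1a
# aligns the fitted cylinder axes and the trochlear-notch projections; step 1b
# matches the cylinder radii and scales each condylar region along the axis;
# step 1c resolves the remaining rotation about the common axis.

# cylinder fitted to the subchondral patch, axis oriented medial -> lateral
femur_cylinder <- function(mesh, anchors) {
  if (!any(mesh$subchondral_mask)) stop("femur has an empty subchondral mask")
  fit <- fit_cylinder(mesh$vertices[mesh$subchondral_mask, , drop = FALSE])
  if (!is.null(anchors$medial_epicondyle) && !is.null(anchors$lateral_epicondyle)) {
    ml <- anchors$lateral_epicondyle - anchors$medial_epicondyle
    if (sum(ml * fit$axis_dir) < 0) fit$axis_dir <- -fit$axis_dir
  }
  fit
}

#' Femur step 1a: align cylinder axes and trochlear-notch projections
#'
#' Fits a cylinder to the subchondral area of each femur, then rigidly moves
#' the moving femur (rotation + translation; scale fixed at 1) so that its
#' cylinder axis is colinear with the reference axis and the projections of
#' the two trochlear notches onto the common axis coincide.
#'
#' @param moving,reference femoral [surface_mesh()] objects with subchondral masks.
#' @param moving_anchors,reference_anchors [anchor_set()] objects with
#'   `trochlear_notch` (and epicondyles, used to orient the axis medial to
#'   lateral).
#' @return a [similarity_transform()] with `scale = 1`; attributes
#'   `moving_fit` and `reference_fit` carry the cylinder fits.
#' @export
femur_align_step1a <- function(moving, reference, moving_anchors,
                               reference_anchors) {
  stopifnot(moving$bone == "femur", reference$bone == "femur")
  if (is.null(moving_anchors$trochlear_notch) ||
      is.null(reference_anchors$trochlear_notch))
    stop("trochlear_notch anchor is required on both femurs")
  fit_m <- femur_cylinder(moving, moving_anchors)
  fit_r <- femur_cylinder(reference, reference_anchors)
  R <- rotation_between(fit_m$axis_dir, fit_r$axis_dir)
  tau_m <- sum((moving_anchors$trochlear_notch - fit_m$axis_point) * fit_m$axis_dir)
  tau_r <- sum((reference_anchors$trochlear_notch - fit_r$axis_point) * fit_r$axis_dir)
  # map the moving notch projection onto the reference notch projection
  t_vec <- fit_r$axis_point + (tau_m) * fit_r$axis_dir -
    as.numeric(R %*% (fit_m$axis_point + tau_m * fit_m$axis_dir)) +
    (tau_r - tau_m) * fit_r$axis_dir
  tr <- similarity_transform(R, t_vec, 1)
  attr(tr, "moving_fit") <- fit_m
  attr(tr, "reference_fit") <- fit_r
  tr
}

#' Femur step 1b: radial and condylar axial scaling
#'
#' After step 1a, scales the moving femur about the common cylinder axis so
#' the two cylinder radii coincide, and scales each condylar region (from the
#' trochlear notch to the medial / lateral epicondyle) separately along the
#' axis so the condylar extents match. The mapping is continuous at the notch
#' projection.
#'
#' @param moving,reference femoral meshes (moving already moved by step 1a).
#' @param fits list with `moving` and `reference` [fit_cylinder()] results in
#'   the common (post-1a) frame; the reference fit defines the axis.
#' @param anchors list with `moving` and `reference` [anchor_set()] objects;
#'   the moving anchors must be in the post-1a frame.
#' @return a [region_scaling()] transform.
#' @export
femur_scale_step1b <- function(moving, reference, fits, anchors) {
  fr <- fits$reference; fm <- fits$moving
  am <- anchors$moving; ar <- anchors$reference
  need <- function(a, nm) {
    for (f in c("trochlear_notch", "medial_epicondyle", "lateral_epicondyle"))
      if (is.null(a[[f]])) stop(nm, " anchors missing ", f)
  }
  need(am, "moving"); need(ar, "reference")
  axis_pt <- fr$axis_point; axis_dir <- fr$axis_dir
  axial <- function(p) sum((p - axis_pt) * axis_dir)
  t0_m <- axial(am$trochlear_notch)
  t0_r <- axial(ar$trochlear_notch)
  ext <- function(a, t0) {
    med <- axial(a$medial_epicondyle) - t0
    lat <- axial(a$lateral_epicondyle) - t0
    if (med >= 0 || lat <= 0)
      stop("epicondyles must lie on opposite sides of the notch along the axis ",
           "(medial at lower axial coordinate)")
    c(medial = -med, lateral = lat)
  }
  ext_m <- ext(am, t0_m); ext_r <- ext(ar, t0_r)
  if (any(ext_m <= 1e-9)) stop("zero axial condylar extent on moving femur")
  region_scaling(axis_point = axis_pt, axis_dir = axis_dir,
                 radial_scale = fr$radius / fm$radius,
                 medial_axial_scale = unname(ext_r["medial"] / ext_m["medial"]),
                 lateral_axial_scale = unname(ext_r["lateral"] / ext_m["lateral"]),
                 boundary_coordinate = t0_r)
}

# mean squared point-to-surface distance from moving subchondral vertices to
# the reference subchondral patch, as a function of rotation about the axis
axial_msd <- function(angle_deg, pts, axis_point, axis_dir, reference, ref_faces) {
  rot <- axial_rotation(axis_point, axis_dir, angle_deg)
  moved <- apply_transform(rot, pts)
  mean(closest_on_mesh(moved, reference, ref_faces)$distance^2)
}

#' Femur step 1c: rotation about the cylinder axis
#'
#' Finds the rotation about the common cylinder axis that minimizes the mean
#' squared point-to-surface distance from the moving subchondral vertices to
#' the reference subchondral patch: a coarse grid search over the full circle
#' at `rotation_search_resolution` degrees, refined by golden-section search.
#' Ties at the grid stage break toward the smallest absolute angle.
#'
#' @param moving,reference femoral meshes in the common frame (steps 1a-1b
#'   applied to `moving`).
#' @param axis_point,axis_dir the common cylinder axis.
#' @param config a [run_config()] (grid resolution).
#' @return an [axial_rotation()] transform; attribute `msd` holds the achieved
#'   mean squared distance.
#' @export
femur_rotate_step1c <- function(moving, reference, axis_point, axis_dir,
                                config = run_config()) {
  if (!any(moving$subchondral_mask) || !any(reference$subchondral_mask))
    stop("subchondral masks must be non-empty on both femurs")
  pts <- moving$vertices[moving$subchondral_mask, , drop = FALSE]
  ref_faces <- subchondral_faces(reference)
  if (!length(ref_faces)) stop("reference subchondral patch has no faces")
  res <- config$rotation_search_resolution
  grid <- seq(-180, 180 - res, by = res)
  vals <- vapply(grid, axial_msd, numeric(1), pts = pts, axis_point = axis_point,
                 axis_dir = axis_dir, reference = reference, ref_faces = ref_faces)
  best_val <- min(vals)
  cand <- grid[vals <= best_val + 1e-15]
  a0 <- cand[which.min(abs(cand))]          # tie-break toward smallest |angle|
  lo <- a0 - res; hi <- a0 + res
  opt <- stats::optimize(axial_msd, c(lo, hi), pts = pts, axis_point = axis_point,
                         axis_dir = axis_dir, reference = reference,
                         ref_faces = ref_faces, tol = 1e-4)
  out <- axial_rotation(axis_point, axis_dir, opt$minimum)
  attr(out, "msd") <- opt$objective
  out
}
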