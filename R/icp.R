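#' Nonrigid ICP with thin-plate-spline deformation
#'
#' Locally deforms a globally aligned moving mesh so its surface closely
#' matches the reference surface. Each iteration (i) projects every moving
#' vertex onto the reference surface (point-to-surface closest point) and
#' (ii) fits a regularized thin-plate spline from a fixed uniform subsample of
#' control vertices to their projections, applying it to all vertices. The
#' regularization (stiffness) decreases over the configured schedule. An
#' update is accepted only if the mean surface distance does not increase, so
#' the recorded distance sequence is non-increasing. A stiffness level ends
#' when the mean per-vertex displacement drops below `icp_tol` or the inner
#' iteration budget is exhausted.
#'
#' @param moving,reference [surface_mesh()] objects, already globally aligned.
#' @param config a [run_config()] (stiffness schedule, control-point count,
#'   tolerance, budget).
#' @return list with `mesh` (deformed moving mesh), `correspondences` (one
#'   reference-surface point per moving vertex), `mean_distance` (final mean
#'   surface-to-surface distance, mm), `history` (mean distance after each
#'   accepted iteration, starting at iteration 0), `converged` (logical).
#' @export
nonrigid_icp <- function(moving, reference, config = run_config()) {
  if (nrow(moving$vertices) == 0) stop("moving mesh is empty")
  if (nrow(reference$faces) == 0) stop("reference mesh has no faces")
  verts <- moving$vertices
  nv <- nrow(verts)
  ctrl <- unique(round(seq(1, nv, length.out = min(config$icp_control_points, nv))))
  cp <- closest_on_mesh(verts, reference)
  d <- mean(cp$distance)
  history <- d
  converged <- FALSE
  for (lambda in config$icp_stiffness) {
    for (inner in seq_len(config$icp_max_inner)) {
      cp <- closest_on_mesh(verts, reference)
      warp <- tryCatch(
        fit_tps(verts[ctrl, , drop = FALSE], cp$points[ctrl, , drop = FALSE],
                regularization = lambda),
        error = function(e) NULL)
      if (is.null(warp)) break
      cand <- apply_transform(warp, verts)
      cand_d <- mean(closest_on_mesh(cand, reference)$distance)
      if (cand_d > d + 1e-12) break            # reject: would increase distance
      disp <- mean(sqrt(rowSums((cand - verts)^2)))
      verts <- cand
      d <- cand_d
      history <- c(history, d)
      if (disp < config$icp_tol) break
    }
  }
  converged <- length(history) > 1 || d < config$icp_tol
  if (!converged)
    warning("nonrigid ICP made no accepted update within the budget")
  out <- moving
  out$vertices <- verts
  cp <- closest_on_mesh(verts, reference)
  list(mesh = out, correspondences = cp$points,
       mean_distance = mean(cp$distance), history = history,
       converged = converged)
}

# greedy farthest-point subsample of row indices
farthest_point_indices <- function(points, k) {
  n <- nrow(points)
  if (k >= n) return(seq_len(n))
  idx <- integer(k)
  idx[1] <- 1L
  d2 <- rowSums(sweep(points, 2, points[1, ])^2)
  for (i in 2:k) {
    idx[i] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(points, 2, points[idx[i], ])^2))
  }
  idx
}

#' Register a moving bone to a reference bone
#'
#' Runs the bone-appropriate chain of global alignment steps (femur: cylinder
#' alignment 1a, radial + condylar scaling 1b, axial rotation 1c; tibia:
#' descriptor similarity, longitudinal scaling), then the nonrigid ICP step.
#' The nonrigid deformation is distilled into a single thin-plate-spline warp
#' fitted on a farthest-point subsample of (post-global position, final
#' position) vertex pairs and appended to the chain, so the full surface
#' transformation can be applied to arbitrary points (phase 2).
#'
#' @param moving,reference [surface_mesh()] objects of the same bone type.
#' @param anchors list with `moving` and `reference` [anchor_set()] objects
#'   (femur: trochlear notch + epicondyles; tibia: longitudinal axis).
#' @param config a [run_config()].
#' @return a [composite_warp()]; attributes: `registered_mesh` (the final
#'   deformed moving mesh), `residuals` (per-step mean distance log),
#'   `mean_distance` (final mean surface distance, mm).
#' @export
register_bone <- function(moving, reference, anchors, config = run_config()) {
  if (moving$bone != reference$bone)
    stop("bone types of moving (", moving$bone, ") and reference (",
         reference$bone, ") differ")
  log <- list()
  chain <- list()
  mesh <- moving
  transform_anchor_points <- function(a, tr) {
    out <- a
    for (f in c("trochlear_notch", "medial_epicondyle", "lateral_epicondyle"))
      if (!is.null(out[[f]]))
        out[[f]] <- as.numeric(apply_transform(tr, matrix(out[[f]], 1)))
    out
  }
  if (moving$bone == "femur") {
    s1a <- femur_align_step1a(mesh, reference, anchors$moving, anchors$reference)
    fit_m <- attr(s1a, "moving_fit"); fit_r <- attr(s1a, "reference_fit")
    mesh$vertices <- apply_transform(s1a, mesh$vertices)
    anch_m <- transform_anchor_points(anchors$moving, s1a)
    # moving cylinder in the common frame: axis maps onto the reference axis
    fit_m_post <- fit_m
    fit_m_post$axis_dir <- fit_r$axis_dir
    fit_m_post$axis_point <- as.numeric(
      apply_transform(s1a, matrix(fit_m$axis_point, 1)))
    chain <- c(chain, list(s1a))
    s1b <- femur_scale_step1b(mesh, reference,
                              fits = list(moving = fit_m_post, reference = fit_r),
                              anchors = list(moving = anch_m,
                                             reference = anchors$reference))
    mesh$vertices <- apply_transform(s1b, mesh$vertices)
    chain <- c(chain, list(s1b))
    s1c <- femur_rotate_step1c(mesh, reference, fit_r$axis_point, fit_r$axis_dir,
                               config)
    mesh$vertices <- apply_transform(s1c, mesh$vertices)
    chain <- c(chain, list(s1c))
    log$global_angle_deg <- s1c$angle_deg
  } else {
    s1 <- tibia_align_step1(mesh, reference)
    mesh$vertices <- apply_transform(s1, mesh$vertices)
    chain <- c(chain, list(s1))
    axes <- list(reference = anchors$reference$longitudinal_axis %||%
                   anchors$moving$longitudinal_axis)
    if (is.null(axes$reference)) stop("tibia registration needs a longitudinal axis")
    s2 <- tibia_scale_step2(mesh, reference, axes)
    mesh$vertices <- apply_transform(s2, mesh$vertices)
    chain <- c(chain, list(s2))
  }
  log$global_mean_distance <- mean(closest_on_mesh(mesh$vertices, reference)$distance)
  pre_icp <- mesh$vertices
  icp <- nonrigid_icp(mesh, reference, config)
  mesh <- icp$mesh
  log$icp_history <- icp$history
  log$final_mean_distance <- icp$mean_distance
  # distill the nonrigid displacement into one TPS for voxel propagation
  k <- min(config$distill_control_points, nrow(pre_icp))
  sel <- farthest_point_indices(pre_icp, k)
  distilled <- fit_tps(pre_icp[sel, , drop = FALSE],
                       mesh$vertices[sel, , drop = FALSE],
                       regularization = config$tps_regularization)
  chain <- c(chain, list(distilled))
  out <- composite_warp(chain)
  attr(out, "registered_mesh") <- mesh
  attr(out, "residuals") <- log
  attr(out, "mean_distance") <- icp$mean_distance
  out
}
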