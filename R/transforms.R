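#' Spatial transforms and the composite warp chain
#'
#' The registration pipeline produces an ordered chain of transforms
#' (similarity, condylar region scaling, axial rotation, thin-plate-spline
#' warp). Each transform maps points from moving space toward reference space;
#' [apply_transform()] applies a single element, [warp_points()] (in the voxel
#' mapping module) applies a whole chain.
#'
#' @param points n x 3 matrix of points (mm).
#' @param transform a transform object.
#' @param ... unused.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, points, ...) UseMethod("apply_transform")

rotation_about_axis <- function(axis, angle_rad) {
  a <- unit3(axis)
  c1 <- cos(angle_rad); s1 <- sin(angle_rad)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * (a %o% a)
}

# minimal rotation taking unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- unit3(u); v <- unit3(v)
  c1 <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s1 <- sqrt(sum(ax^2))
  if (s1 < 1e-12) {
    if (c1 > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- unit3(perp - sum(perp * u) * u)
    return(rotation_about_axis(perp, pi))
  }
  rotation_about_axis(ax / s1, atan2(s1, c1))
}

#' Similarity transform (rotation, translation, isotropic scale)
#'
#' Applies as `p -> scale * rotation %*% p + translation`.
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation 3-vector (mm).
#' @param scale positive scalar.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal to 1e-9")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation), scale = scale),
            class = c("similarity_transform", "knee_transform"))
}

#' @export
apply_transform.similarity_transform <- function(transform, points, ...) {
  points <- as_points3(points)
  sweep(transform$scale * points %*% t(transform$rotation), 2,
        transform$translation, "+")
}

invert_similarity <- function(tr) {
  Rinv <- t(tr$rotation)
  similarity_transform(Rinv, -as.numeric(Rinv %*% tr$translation) / tr$scale,
                       1 / tr$scale)
}

#' Condylar region scaling about a cylinder axis
#'
#' Radial scaling about the axis combined with piecewise-linear axial scaling:
#' positions along the axis are scaled separately on each side of the
#' trochlear-notch projection (`boundary_coordinate`), continuously at the
#' boundary. The medial side is the one with smaller axial coordinate (the
#' axis points medial to lateral).
#'
#' @param axis_point,axis_dir cylinder axis (point on axis, unit direction).
#' @param radial_scale,medial_axial_scale,lateral_axial_scale positive scalars.
#' @param boundary_coordinate axial coordinate (mm) of the notch projection,
#'   measured as `dot(p - axis_point, axis_dir)`.
#' @return An object of class `region_scaling`.
#' @export
region_scaling <- function(axis_point, axis_dir, radial_scale,
                           medial_axial_scale, lateral_axial_scale,
                           boundary_coordinate) {
  sc <- c(radial_scale, medial_axial_scale, lateral_axial_scale)
  if (any(!is.finite(sc)) || any(sc <= 0)) stop("all scales must be positive")
  structure(list(axis_point = as.numeric(axis_point), axis_dir = unit3(axis_dir),
                 radial_scale = radial_scale,
                 medial_axial_scale = medial_axial_scale,
                 lateral_axial_scale = lateral_axial_scale,
                 boundary_coordinate = boundary_coordinate),
            class = c("region_scaling", "knee_transform"))
}

#' @export
apply_transform.region_scaling <- function(transform, points, ...) {
  points <- as_points3(points)
  q <- transform$axis_point; d <- transform$axis_dir
  rel <- sweep(points, 2, q)
  tcoord <- as.numeric(rel %*% d)
  radial <- rel - tcoord %o% d
  t0 <- transform$boundary_coordinate
  s_ax <- ifelse(tcoord < t0, transform$medial_axial_scale,
                 transform$lateral_axial_scale)
  tnew <- t0 + s_ax * (tcoord - t0)
  sweep(transform$radial_scale * radial + tnew %o% d, 2, q, "+")
}

#' Rotation about a cylinder axis
#' @param axis_point,axis_dir the axis (point, unit direction).
#' @param angle_deg rotation angle in degrees (right-handed about `axis_dir`).
#' @return An object of class `axial_rotation`.
#' @export
axial_rotation <- function(axis_point, axis_dir, angle_deg) {
  structure(list(axis_point = as.numeric(axis_point), axis_dir = unit3(axis_dir),
                 angle_deg = angle_deg),
            class = c("axial_rotation", "knee_transform"))
}

#' @export
apply_transform.axial_rotation <- function(transform, points, ...) {
  points <- as_points3(points)
  R <- rotation_about_axis(transform$axis_dir, transform$angle_deg * pi / 180)
  rel <- sweep(points, 2, transform$axis_point)
  sweep(rel %*% t(R), 2, transform$axis_point, "+")
}

#' Fit a 3D thin-plate spline warp
#'
#' Solves the standard landmark TPS system with kernel `U(r) = r` (the 3D
#' biharmonic kernel) plus an affine part. With `regularization = 0` the warp
#' interpolates every control pair exactly; as regularization grows the warp
#' tends to the least-squares affine fit.
#'
#' @param source_points,target_points paired n x 3 control points (n >= 4,
#'   non-coplanar, no duplicated source points).
#' @param regularization nonnegative scalar added to the kernel diagonal.
#' @return An object of class `tps_warp` with `affine_part` (3 x 4: column 1
#'   the offset, columns 2:4 the linear map), `kernel_weights` (n x 3),
#'   `control_points_source/target`, `bending_energy`.
#' @export
fit_tps <- function(source_points, target_points, regularization = 0) {
  src <- as_points3(source_points, "source_points")
  tgt <- as_points3(target_points, "target_points")
  n <- nrow(src)
  if (nrow(tgt) != n) stop("source and target point counts differ")
  if (n < 4) stop("TPS needs >= 4 control points")
  if (regularization < 0) stop("regularization must be nonnegative")
  dmat <- as.matrix(stats::dist(src))
  if (min(dmat[upper.tri(dmat)]) < 1e-9) stop("duplicate source control points")
  centered <- sweep(src, 2, colMeans(src))
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) stop("source control points are coplanar")
  K <- dmat
  P <- cbind(1, src)
  A <- rbind(cbind(K + regularization * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  for (i in 1:2) sol <- sol + solve(A, rhs - A %*% sol)  # iterative refinement
  w <- sol[seq_len(n), , drop = FALSE]
  a <- sol[n + 1:4, , drop = FALSE]          # 4 x 3: offset then linear rows
  be <- sum(abs(colSums(w * (K %*% w))))
  structure(list(control_points_source = src, control_points_target = tgt,
                 kernel_weights = w, affine_part = t(a),
                 regularization = regularization, bending_energy = be),
            class = c("tps_warp", "knee_transform"))
}

#' @export
apply_transform.tps_warp <- function(transform, points, ...) {
  points <- as_points3(points)
  src <- transform$control_points_source
  w <- transform$kernel_weights
  At <- t(transform$affine_part)                     # 4 x 3
  out <- cbind(1, points) %*% At
  # per-control distances computed directly (no expanded-square cancellation)
  for (j in seq_len(nrow(src))) {
    u <- sqrt((points[, 1] - src[j, 1])^2 + (points[, 2] - src[j, 2])^2 +
                (points[, 3] - src[j, 3])^2)
    out <- out + u %o% w[j, ]
  }
  out
}

#' Composite warp chain
#'
#' Ordered list of transforms applied first-to-last; the output of the
#' surface-registration phase and the input of the voxel-propagation phase.
#' @param ... transform objects (or a single list of them).
#' @return An object of class `composite_warp`.
#' @export
composite_warp <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "knee_transform")) parts <- parts[[1]]
  ok <- vapply(parts, inherits, logical(1), "knee_transform")
  if (!all(ok)) stop("all chain elements must be transforms")
  structure(list(transforms = parts), class = "composite_warp")
}

#' @export
apply_transform.composite_warp <- function(transform, points, ...) {
  for (tr in transform$transforms) points <- apply_transform(tr, points)
  points
}

#' @export
print.composite_warp <- function(x, ...) {
  cat("composite_warp with", length(x$transforms), "transforms:",
      paste(vapply(x$transforms, function(t) class(t)[1], character(1)),
            collapse = " -> "), "\n")
  invisible(x)
}

#' Save or load a composite warp as JSON-like YAML
#'
#' Full numeric precision; each chain element is stored with its class tag.
#' @param warp a [composite_warp()].
#' @param path output path.
#' @return `path` / the warp.
#' @export
write_warp <- function(warp, path) {
  ser <- lapply(warp$transforms, function(tr) {
    out <- lapply(unclass(tr), function(v) {
      if (is.matrix(v)) list(.matrix = dim(v), data = as.numeric(v)) else v
    })
    out$.class <- class(tr)[1]
    out
  })
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @rdname write_warp
#' @export
read_warp <- function(path) {
  ser <- yaml::read_yaml(path)
  parts <- lapply(ser, function(el) {
    cls <- el$.class
    el$.class <- NULL
    el <- lapply(el, function(v) {
      if (is.list(v) && !is.null(v$.matrix))
        matrix(as.numeric(v$data), v$.matrix[1], v$.matrix[2])
      else if (is.list(v)) as.numeric(unlist(v)) else v
    })
    structure(el, class = c(cls, "knee_transform"))
  })
  composite_warp(parts)
}
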