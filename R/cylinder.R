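#' Fit a cylinder to a surface patch
#'
#' Orthogonal-distance least squares: minimizes the sum of squared differences
#' between each point's distance to the axis and the radius. For a fixed axis
#' the optimal radius is the mean distance to the axis, so the optimization
#' runs over the 4 degrees of freedom of the axis (direction on the sphere and
#' a point constrained to the plane through the patch centroid orthogonal to
#' the direction), initialized from the principal directions of the patch.
#'
#' @param points n x 3 matrix (mm); >= 6 points spanning a curved patch.
#' @param starts optional list of unit 3-vectors used as initial axis
#'   directions; defaults to the three principal directions of the patch.
#' @return An object of class `cylinder_fit` with `axis_point`, `axis_dir`
#'   (unit, sign canonicalized so its largest component is positive),
#'   `radius` (mm) and `rms_residual` (mm).
#' @export
fit_cylinder <- function(points, starts = NULL) {
  pts <- as_points3(points)
  n <- nrow(pts)
  if (n < 6) stop("cylinder fit needs >= 6 points")
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  sv <- svd(centered, nu = 0)
  scale0 <- sv$d[1] / sqrt(n)
  # coplanar patches admit no finite cylinder
  if (sv$d[3] / sqrt(n) < 1e-7 * max(scale0, 1))
    stop("degenerate geometry: points are coplanar within tolerance")

  obj <- function(par, frame) {
    # par = (theta, phi, u, v): axis direction in spherical coordinates,
    # axis point = ctr + u * e1 + v * e2 in the direction-orthogonal frame
    d <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    q <- ctr + par[3] * frame[, 1] + par[4] * frame[, 2]
    rel <- sweep(pts, 2, q)
    tc <- as.numeric(rel %*% d)
    r <- sqrt(pmax(rowSums(rel^2) - tc^2, 0))
    sum((r - mean(r))^2)
  }
  ortho_frame <- function(d) {
    e1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit3(e1 - sum(e1 * d) * d)
    cbind(e1, c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
                d[1] * e1[2] - d[2] * e1[1]))
  }
  if (is.null(starts)) starts <- lapply(1:3, function(k) sv$v[, k])
  best <- NULL
  for (d0 in starts) {
    d0 <- unit3(d0)
    if (d0[3] < 0) d0 <- -d0
    par0 <- c(acos(min(max(d0[3], -1), 1)), atan2(d0[2], d0[1]), 0, 0)
    fr <- ortho_frame(d0)
    fit <- tryCatch(
      stats::optim(par0, obj, frame = fr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
      best$frame <- fr
    }
  }
  if (is.null(best)) stop("cylinder optimization failed to converge")
  par <- best$par
  d <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  q <- ctr + par[3] * best$frame[, 1] + par[4] * best$frame[, 2]
  rel <- sweep(pts, 2, q)
  tc <- as.numeric(rel %*% d)
  r <- sqrt(pmax(rowSums(rel^2) - tc^2, 0))
  radius <- mean(r)
  if (!is.finite(radius) || radius <= 0) stop("cylinder fit returned invalid radius")
  # canonical sign: largest-magnitude component positive
  if (d[which.max(abs(d))] < 0) d <- -d
  # re-anchor the axis point at the centroid's axial position
  q <- q + sum((ctr - q) * d) * d
  structure(list(axis_point = q, axis_dir = d, radius = radius,
                 rms_residual = sqrt(mean((r - radius)^2)),
                 objective = best$value),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("cylinder_fit: radius %.4f mm, rms residual %.3g mm, axis (%.4f, %.4f, %.4f)\n",
              x$radius, x$rms_residual, x$axis_dir[1], x$axis_dir[2], x$axis_dir[3]))
  invisible(x)
}
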