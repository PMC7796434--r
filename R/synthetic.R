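#' Specification of a synthetic bone mesh
#'
#' Idealized bone-like geometry with analytic registration ground truth. The
#' femur is a two-lobed sweep around a medio-lateral cylinder axis: the
#' subchondral (condylar) patch lies exactly on a cylinder of known radius,
#' interrupted centrally by a trochlear-notch indentation. The tibia is a
#' tapered extrusion of an elliptical plateau along the longitudinal axis,
#' with a slightly dished top carrying two elliptical subchondral patches of
#' different sizes (medial larger, as in anatomy).
#'
#' @param bone `"femur"` or `"tibia"`.
#' @param condyle_radius femur: subchondral cylinder radius (mm).
#' @param width femur: medio-lateral extent (mm).
#' @param notch_halfwidth,notch_depth femur: trochlear-notch size (mm).
#' @param subchondral_arc_deg femur: angular half-extent of the subchondral
#'   arc around the cylinder axis (degrees).
#' @param plateau_ml,plateau_ap tibia: plateau half-axes (mm).
#' @param shaft_length tibia: proximal segment length along the axis (mm).
#' @param taper tibia: fractional radius reduction at the distal end.
#' @param dome_depth tibia: dishing depth of the plateau (mm).
#' @param resolution list of angular/axial/radial vertex counts.
#' @param noise_sd isotropic Gaussian vertex jitter (mm, default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return An object of class `synthetic_bone_spec`.
#' @export
synthetic_bone_spec <- function(bone = c("femur", "tibia"),
                                condyle_radius = 21, width = 76,
                                notch_halfwidth = 9, notch_depth = 7,
                                subchondral_arc_deg = 100,
                                plateau_ml = 38, plateau_ap = 26,
                                shaft_length = 60, taper = 0.35,
                                dome_depth = 3,
                                resolution = NULL, noise_sd = 0, seed = 1L) {
  bone <- match.arg(bone)
  if (is.null(resolution))
    resolution <- if (bone == "femur") list(n_theta = 48L, n_axis = 36L)
                  else list(n_theta = 48L, n_axis = 22L, n_radial = 10L)
  dims <- c(condyle_radius, width, notch_halfwidth, notch_depth, plateau_ml,
            plateau_ap, shaft_length, dome_depth)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all dimensions must be positive")
  if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)")
  if (subchondral_arc_deg <= 10 || subchondral_arc_deg >= 170)
    stop("subchondral_arc_deg must be in (10, 170)")
  if (resolution$n_theta < 8 || resolution$n_axis < 4)
    stop("resolution too low for a watertight mesh")
  structure(list(bone = bone, condyle_radius = condyle_radius, width = width,
                 notch_halfwidth = notch_halfwidth, notch_depth = notch_depth,
                 subchondral_arc_deg = subchondral_arc_deg,
                 plateau_ml = plateau_ml, plateau_ap = plateau_ap,
                 shaft_length = shaft_length, taper = taper,
                 dome_depth = dome_depth, resolution = resolution,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_bone_spec")
}

# closed sweep surface: rings x thetas + two cap apices; returns faces too
sweep_mesh_faces <- function(n_rings, n_theta) {
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", n_rings - 1L)
  for (i in seq_len(n_rings - 1L)) {
    j <- seq_len(n_theta)
    faces[[i]] <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                        cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  do.call(rbind, faces)
}

make_femur_mesh <- function(spec) {
  nt <- spec$resolution$n_theta; nx <- spec$resolution$n_axis
  R <- spec$condyle_radius
  hw <- spec$width / 2
  alpha <- spec$subchondral_arc_deg * pi / 180
  alpha_n <- 0.6 * alpha
  xs <- seq(-hw, hw, length.out = nx)
  thetas <- seq(-pi, pi - 2 * pi / nt, length.out = nt)
  # profile direction: theta = 0 points distal (-z), +theta toward posterior (+y)
  radius_at <- function(theta, x) {
    r <- rep(R, length(theta))
    gx <- ifelse(abs(x) < spec$notch_halfwidth,
                 cos(pi * x / (2 * spec$notch_halfwidth))^2, 0)
    ht <- ifelse(abs(theta) < alpha_n, cos(pi * theta / (2 * alpha_n))^2, 0)
    r <- r - spec$notch_depth * gx * ht
    out <- abs(theta) > alpha
    u <- (abs(theta[out]) - alpha) / (pi - alpha)
    r[out] <- r[out] - 0.35 * R * sin(pi * u / 2)^2
    r
  }
  verts <- matrix(0, nx * nt, 3)
  mask <- logical(nx * nt)
  for (i in seq_len(nx)) {
    r <- radius_at(thetas, xs[i])
    rows <- (i - 1L) * nt + seq_len(nt)
    verts[rows, ] <- cbind(xs[i], r * sin(thetas), -r * cos(thetas))
    band <- abs(xs[i]) >= spec$notch_halfwidth + 1e-9 &
      abs(xs[i]) <= hw - spec$width * 0.06
    mask[rows] <- band & abs(thetas) <= alpha - 1e-9
  }
  faces <- sweep_mesh_faces(nx, nt)
  apex_m <- nrow(verts) + 1L; apex_l <- nrow(verts) + 2L
  verts <- rbind(verts, c(-hw, 0, 0), c(hw, 0, 0))
  j <- seq_len(nt); jn <- (j %% nt) + 1L
  faces <- rbind(faces,
                 cbind(apex_m, j, jn),                                  # medial cap
                 cbind(apex_l, (nx - 1L) * nt + jn, (nx - 1L) * nt + j)) # lateral cap
  mask <- c(mask, FALSE, FALSE)
  anchors <- anchor_set(
    trochlear_notch = c(0, 0, -(R - spec$notch_depth)),
    medial_epicondyle = c(-hw, 0, 0),
    lateral_epicondyle = c(hw, 0, 0))
  list(vertices = verts, faces = faces, mask = mask, anchors = anchors,
       cylinder = list(axis_point = c(0, 0, 0), axis_dir = c(1, 0, 0),
                       radius = R))
}

make_tibia_mesh <- function(spec) {
  nt <- spec$resolution$n_theta
  nz <- spec$resolution$n_axis
  nr <- spec$resolution$n_radial %||% 10L
  a <- spec$plateau_ml; b <- spec$plateau_ap; L <- spec$shaft_length
  thetas <- seq(-pi, pi - 2 * pi / nt, length.out = nt)
  rho <- a * b / sqrt((b * cos(thetas))^2 + (a * sin(thetas))^2)
  zs <- seq(0, -L, length.out = nz)
  verts <- matrix(0, nz * nt, 3)
  for (i in seq_len(nz)) {
    shrink <- 1 - spec$taper * (-zs[i] / L)
    rows <- (i - 1L) * nt + seq_len(nt)
    verts[rows, ] <- cbind(shrink * rho * cos(thetas),
                           shrink * rho * sin(thetas), zs[i])
  }
  faces <- sweep_mesh_faces(nz, nt)
  mask <- logical(nz * nt)
  # bottom cap (flat fan)
  apex_b <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, -L))
  j <- seq_len(nt); jn <- (j %% nt) + 1L
  faces <- rbind(faces, cbind(apex_b, (nz - 1L) * nt + jn, (nz - 1L) * nt + j))
  mask <- c(mask, FALSE)
  # dished top cap: concentric rings s = (nr-1)/nr .. 1/nr plus centre vertex
  top_rows <- list()
  prev_ring <- seq_len(nt)                       # rim = first sweep ring (z = 0)
  for (q in rev(seq_len(nr - 1L))) {
    s <- q / nr
    ring <- nrow(verts) + seq_len(nt)
    zdome <- -spec$dome_depth * (1 - s^2)
    verts <- rbind(verts, cbind(s * rho * cos(thetas), s * rho * sin(thetas),
                                zdome))
    mask <- c(mask, logical(nt))
    faces <- rbind(faces,
                   cbind(prev_ring[j], prev_ring[jn], ring[jn]),
                   cbind(prev_ring[j], ring[jn], ring[j]))
    prev_ring <- ring
  }
  centre <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, -spec$dome_depth))
  mask <- c(mask, FALSE)
  faces <- rbind(faces, cbind(centre, prev_ring[j], prev_ring[jn]))
  # subchondral patches on the top cap: medial larger, offsets break symmetry
  med <- c(-0.45 * a, 0.10 * b); med_ax <- c(0.40 * a, 0.72 * b)
  lat <- c(0.45 * a, -0.15 * b); lat_ax <- c(0.32 * a, 0.60 * b)
  top <- verts[, 3] > -spec$dome_depth - 1e-9 & seq_len(nrow(verts)) > nz * nt
  top[seq_len(nt)] <- TRUE                       # include the rim ring
  in_ell <- function(p, c0, ax)
    ((p[, 1] - c0[1]) / ax[1])^2 + ((p[, 2] - c0[2]) / ax[2])^2 <= 1
  mask[top] <- in_ell(verts[top, , drop = FALSE], med, med_ax) |
    in_ell(verts[top, , drop = FALSE], lat, lat_ax)
  anchors <- anchor_set(longitudinal_axis = c(0, 0, 1))
  list(vertices = verts, faces = faces, mask = mask, anchors = anchors)
}

#' Generate a synthetic labeled bone mesh with ground-truth anchors
#'
#' Deterministic per spec (and seed, when vertex jitter is enabled). The femur
#' subchondral patch lies exactly on a cylinder of `condyle_radius` (before
#' jitter), so cylinder-fit ground truth is analytic.
#'
#' @param spec a [synthetic_bone_spec()].
#' @return list with `mesh` (a watertight [surface_mesh()]), `anchors`
#'   (an [anchor_set()]), and for the femur `cylinder` (true axis and radius).
#' @export
make_bone_mesh <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bone_spec"))
  raw <- if (spec$bone == "femur") make_femur_mesh(spec) else make_tibia_mesh(spec)
  verts <- raw$vertices
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    verts <- verts + matrix(rnorm(length(verts), sd = spec$noise_sd),
                            ncol = 3)
  }
  mesh <- surface_mesh(verts, raw$faces, raw$mask, bone = spec$bone,
                       side = "right")
  out <- list(mesh = mesh, anchors = raw$anchors)
  if (!is.null(raw$cylinder)) out$cylinder <- raw$cylinder
  out
}

#' Smooth synthetic deformation with known inverse
#'
#' A similarity transform composed with a sum of low-frequency Gaussian
#' radial-basis displacement bumps: `y = similarity(x + sum_b a_b
#' exp(-|x - c_b|^2 / (2 w_b^2)))`. Bump amplitudes are capped at
#' `0.5 * width` so the warp stays diffeomorphic and the inverse (fixed-point
#' iteration) converges.
#'
#' @param centers n_bumps x 3 matrix of bump centres (mm).
#' @param amplitudes n_bumps x 3 matrix of displacement vectors (mm).
#' @param widths length-n_bumps vector of Gaussian widths (mm).
#' @param similarity a [similarity_transform()] applied after the bumps.
#' @return An object of class `synthetic_deformation`.
#' @export
deformation_spec <- function(centers = matrix(numeric(), 0, 3),
                             amplitudes = matrix(numeric(), 0, 3),
                             widths = numeric(),
                             similarity = similarity_transform()) {
  centers <- if (nrow(as.matrix(centers))) as_points3(centers) else matrix(numeric(), 0, 3)
  amplitudes <- if (nrow(as.matrix(amplitudes))) as_points3(amplitudes, "amplitudes")
                else matrix(numeric(), 0, 3)
  if (nrow(centers) != nrow(amplitudes) || nrow(centers) != length(widths))
    stop("centers, amplitudes and widths must agree in length")
  if (length(widths) && any(widths <= 0)) stop("widths must be positive")
  amp_norm <- if (nrow(amplitudes)) sqrt(rowSums(amplitudes^2)) else numeric()
  if (length(widths) && any(amp_norm / widths > 0.5))
    stop("amplitude/width ratio exceeds the diffeomorphic bound (0.5)")
  structure(list(centers = centers, amplitudes = amplitudes, widths = widths,
                 similarity = similarity),
            class = "synthetic_deformation")
}

#' Random smooth deformation
#'
#' @param domain_center,domain_radius region (mm) in which bump centres are drawn.
#' @param n_bumps number of Gaussian bumps.
#' @param amplitude maximum displacement per bump (mm).
#' @param width Gaussian width (mm); must satisfy `amplitude / width <= 0.5`.
#' @param similarity a [similarity_transform()] composed after the bumps.
#' @param seed integer seed.
#' @return a [deformation_spec()].
#' @export
random_deformation <- function(domain_center = c(0, 0, 0), domain_radius = 40,
                               n_bumps = 4, amplitude = 1.5, width = 25,
                               similarity = similarity_transform(), seed = 1L) {
  set.seed(seed)
  centers <- sweep(matrix(runif(3 * n_bumps, -domain_radius, domain_radius),
                          ncol = 3), 2, domain_center, "+")
  dirs <- matrix(rnorm(3 * n_bumps), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- dirs * runif(n_bumps, 0.5 * amplitude, amplitude)
  deformation_spec(centers, amps, rep(width, n_bumps), similarity)
}

bump_displacement <- function(def, points) {
  disp <- matrix(0, nrow(points), 3)
  for (b in seq_len(nrow(def$centers))) {
    d2 <- rowSums(sweep(points, 2, def$centers[b, ])^2)
    disp <- disp + exp(-d2 / (2 * def$widths[b]^2)) %o% def$amplitudes[b, ]
  }
  disp
}

#' Apply / invert a synthetic deformation
#' @param def a [deformation_spec()].
#' @param points n x 3 matrix (mm).
#' @param tol fixed-point tolerance for the inverse (mm).
#' @return n x 3 matrix of mapped points.
#' @export
apply_deformation <- function(def, points) {
  points <- as_points3(points)
  apply_transform(def$similarity, points + bump_displacement(def, points))
}

#' @rdname apply_deformation
#' @export
invert_deformation <- function(def, points, tol = 1e-9) {
  points <- as_points3(points)
  y <- apply_transform(invert_similarity(def$similarity), points)
  x <- y
  for (it in seq_len(100)) {
    xn <- y - bump_displacement(def, x)
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  x
}

#' Deform a synthetic bone (mesh + anchors) by a known deformation
#' @param bone output of [make_bone_mesh()].
#' @param def a [deformation_spec()].
#' @return the deformed bone (mesh, anchors, mask preserved).
#' @export
deform_bone <- function(bone, def) {
  out <- bone
  out$mesh$vertices <- apply_deformation(def, bone$mesh$vertices)
  a <- bone$anchors
  mapp <- function(p) if (is.null(p)) NULL else as.numeric(apply_deformation(def, matrix(p, 1)))
  out$anchors <- anchor_set(
    trochlear_notch = mapp(a$trochlear_notch),
    medial_epicondyle = mapp(a$medial_epicondyle),
    lateral_epicondyle = mapp(a$lateral_epicondyle),
    longitudinal_axis = if (is.null(a$longitudinal_axis)) NULL else
      as.numeric(def$similarity$rotation %*% a$longitudinal_axis))
  out$cylinder <- NULL                       # no longer exact after deformation
  out
}

#' Rasterize a synthetic CT volume with calibration-phantom rods
#'
#' Voxels inside the bone mesh get `HU = (bmd_field - intercept) / slope`
#' (plus optional Gaussian noise); the background sits at a soft-tissue value;
#' constant-density phantom rods are rendered as cylinders beside the bone
#' (parallel to the scan axis z). Rod ROI samples are measured from the rod
#' interiors of the rendered volume, exactly as a user would place ROIs.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param bmd_field function taking an n x 3 matrix (mm) and returning BMD
#'   (mg/cc) per point.
#' @param spacing voxel spacing (mm), length 3.
#' @param calibration_truth list with `slope` (mg/cc per HU) and `intercept`
#'   (mg/cc): the ground-truth calibration line.
#' @param rod_densities known rod densities (mg/cc).
#' @param rod_radius rod radius (mm).
#' @param noise_sd Gaussian HU noise (default 0).
#' @param background_hu background attenuation (default -70, soft tissue/fat).
#' @param margin padding around the bone (mm).
#' @param seed integer seed (used when `noise_sd > 0`).
#' @return list with `volume` (HU [ct_volume()]), `samples` (list of
#'   [phantom_sample()]), `truth_bmd` ([ct_volume()] in mg/cc, `NaN` outside
#'   the bone), `inside` (logical array: bone interior).
#' @export
make_ct <- function(mesh, bmd_field, spacing = c(1, 1, 1),
                    calibration_truth = list(slope = 0.8, intercept = -5),
                    rod_densities = c(0, 75, 150, 300),
                    rod_radius = 4, noise_sd = 0, background_hu = -70,
                    margin = 8, seed = 1L) {
  stopifnot_watertight(mesh)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  if (any(spacing > (bb_hi - bb_lo)))
    stop("spacing is larger than the bone extent")
  slope <- calibration_truth$slope; intercept <- calibration_truth$intercept
  n_rods <- length(rod_densities)
  rod_y <- bb_lo[2] - margin / 2 - rod_radius
  rod_x <- seq(bb_lo[1], bb_hi[1], length.out = n_rods + 2)[2:(n_rods + 1)]
  lo <- bb_lo - margin - c(0, 2 * rod_radius + margin / 2, 0)
  hi <- bb_hi + margin
  dims <- as.integer(ceiling((hi - lo) / spacing))
  vol <- ct_volume(array(background_hu, dim = dims), spacing,
                   origin = lo + spacing / 2)
  centers <- voxel_centers(vol)
  # bone interior
  in_bb <- centers[, 1] >= bb_lo[1] & centers[, 1] <= bb_hi[1] &
    centers[, 2] >= bb_lo[2] & centers[, 2] <= bb_hi[2] &
    centers[, 3] >= bb_lo[3] & centers[, 3] <= bb_hi[3]
  inside <- logical(nrow(centers))
  inside[in_bb] <- points_in_mesh(centers[in_bb, , drop = FALSE], mesh)
  hu <- rep(background_hu, nrow(centers))
  truth <- rep(NaN, nrow(centers))
  if (any(inside)) {
    bmd <- bmd_field(centers[inside, , drop = FALSE])
    truth[inside] <- bmd
    hu[inside] <- (bmd - intercept) / slope
  }
  rod_voxels <- vector("list", n_rods)
  for (r in seq_len(n_rods)) {
    d2 <- (centers[, 1] - rod_x[r])^2 + (centers[, 2] - rod_y)^2
    in_rod <- d2 < rod_radius^2
    hu[in_rod] <- (rod_densities[r] - intercept) / slope
    rod_voxels[[r]] <- which(d2 < (0.7 * rod_radius)^2)   # ROI core
  }
  if (noise_sd > 0) {
    set.seed(seed)
    hu <- hu + rnorm(length(hu), sd = noise_sd)
  }
  vol$voxels <- array(hu, dim = dims)
  samples <- lapply(seq_len(n_rods), function(r)
    phantom_sample(mean(hu[rod_voxels[[r]]]), rod_densities[r],
                   length(rod_voxels[[r]])))
  truth_vol <- ct_volume(array(truth, dim = dims), spacing,
                         origin = lo + spacing / 2, units = "mg/cc")
  list(volume = vol, samples = samples, truth_bmd = truth_vol,
       inside = array(inside, dim = dims))
}

#' Simulate repeated-measures BMD tables with known variance components
#'
#' `value(cell, knee, repeat) = cell_mean + knee_effect + error`, with
#' `knee_effect ~ N(0, sigma_between^2)` per (cell, knee), shared across
#' settings and repeats, and independent `error ~ N(0, sigma_setting^2)` per
#' observation. The ground-truth ICC of a setting is
#' `sigma_between^2 / (sigma_between^2 + sigma_setting^2)`.
#'
#' @param n_cells,n_knees,n_repeats table dimensions.
#' @param sigma_between between-knee SD (mg/cc).
#' @param sigma_error residual SD (mg/cc), used when `per_setting_sigmas` is NULL.
#' @param per_setting_sigmas named vector of residual SDs, one per setting.
#' @param cell_mean_range range of the per-cell mean BMD (mg/cc).
#' @param seed integer seed (deterministic per seed).
#' @return list with `settings` (named list of [repeated_measures()]),
#'   `truth_icc` (named vector), `sigma_between`, `per_setting_sigmas`.
#' @export
make_repeated_dataset <- function(n_cells, n_knees = 10, n_repeats = 2,
                                  sigma_between = 30, sigma_error = 10,
                                  per_setting_sigmas = NULL,
                                  cell_mean_range = c(100, 400), seed = 1L) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  if (n_cells < 1 || n_knees < 2) stop("need >= 1 cell and >= 2 knees")
  if (sigma_between < 0 || sigma_error < 0) stop("variances must be nonnegative")
  if (is.null(per_setting_sigmas))
    per_setting_sigmas <- c(setting1 = sigma_error)
  if (is.null(names(per_setting_sigmas)))
    names(per_setting_sigmas) <- paste0("setting", seq_along(per_setting_sigmas))
  set.seed(seed)
  cell_means <- runif(n_cells, cell_mean_range[1], cell_mean_range[2])
  knee_eff <- matrix(rnorm(n_cells * n_knees, sd = sigma_between),
                     n_cells, n_knees)
  base <- array(rep(cell_means, times = n_knees * n_repeats),
                dim = c(n_cells, n_knees, n_repeats)) +
    array(rep(knee_eff, times = n_repeats), dim = c(n_cells, n_knees, n_repeats))
  settings <- lapply(per_setting_sigmas, function(sig) {
    repeated_measures(base + array(rnorm(length(base), sd = sig),
                                   dim = dim(base)))
  })
  truth <- sigma_between^2 / (sigma_between^2 + per_setting_sigmas^2)
  list(settings = settings, truth_icc = truth,
       sigma_between = sigma_between, per_setting_sigmas = per_setting_sigmas)
}
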