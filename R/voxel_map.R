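#' BMD point cloud
#'
#' Voxel-centre positions with their BMD values; produced in moving space by
#' [extract_bone_voxels()] and carried into reference space by [warp_points()].
#' @param points n x 3 matrix (mm).
#' @param values length-n numeric vector (mg/cc).
#' @return An object of class `bmd_point_cloud`.
#' @export
bmd_point_cloud <- function(points, values) {
  points <- if (nrow(as.matrix(points)) == 0) matrix(numeric(), 0, 3)
            else as_points3(points)
  values <- as.numeric(values)
  if (length(values) != nrow(points)) stop("points and values lengths differ")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  structure(list(points = points, values = values), class = "bmd_point_cloud")
}

#' @export
print.bmd_point_cloud <- function(x, ...) {
  cat(sprintf("bmd_point_cloud: %d points, BMD %.4g .. %.4g mg/cc\n",
              nrow(x$points),
              if (length(x$values)) min(x$values) else NA,
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Extract bone-interior voxels as a BMD point cloud
#'
#' Returns exactly the voxel centres strictly inside the watertight bone mesh
#' (ray-parity test), with their calibrated BMD values, in moving space.
#' Voxels outside the mesh bounding box are rejected cheaply first.
#'
#' @param volume a calibrated [ct_volume()] (mg/cc).
#' @param mesh a watertight [surface_mesh()].
#' @return a [bmd_point_cloud()].
#' @export
extract_bone_voxels <- function(volume, mesh) {
  stopifnot(inherits(volume, "ct_volume"))
  stopifnot_watertight(mesh)
  centers <- voxel_centers(volume)
  vals <- as.vector(volume$voxels)
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  in_bb <- centers[, 1] >= bb_lo[1] & centers[, 1] <= bb_hi[1] &
    centers[, 2] >= bb_lo[2] & centers[, 2] <= bb_hi[2] &
    centers[, 3] >= bb_lo[3] & centers[, 3] <= bb_hi[3]
  if (!any(in_bb)) return(bmd_point_cloud(matrix(numeric(), 0, 3), numeric()))
  cand <- centers[in_bb, , drop = FALSE]
  inside <- points_in_mesh(cand, mesh)
  bmd_point_cloud(cand[inside, , drop = FALSE], vals[in_bb][inside])
}

#' Warp a BMD point cloud into reference space
#'
#' Applies a transform chain in order to each point; the BMD values are
#' carried unchanged (no resampling, no density rescaling).
#' @param cloud a [bmd_point_cloud()].
#' @param warp a [composite_warp()] or single transform.
#' @return the warped [bmd_point_cloud()].
#' @export
warp_points <- function(cloud, warp) {
  stopifnot(inherits(cloud, "bmd_point_cloud"))
  if (!inherits(warp, "composite_warp") && !inherits(warp, "knee_transform"))
    stop("warp must be a composite_warp or a transform")
  if (nrow(cloud$points) == 0) return(cloud)
  cloud$points <- apply_transform(warp, cloud$points)
  cloud
}

#' Build the fixed cell grid of a reference bone
#'
#' Axis-aligned grid of isotropic half-open cubic cells `[lo, hi)` covering
#' the reference mesh bounding box, anchored at the bounding-box minimum
#' corner (deterministic). A cell is interior when its centre lies strictly
#' inside the reference surface; interior cells form the map support.
#'
#' @param reference a watertight reference [surface_mesh()].
#' @param cell_size isotropic cell side (mm), default 2.
#' @return An object of class `cell_grid` with `cell_size`, `origin`, `dims`,
#'   `interior_mask` (logical array of dims).
#' @export
build_cell_grid <- function(reference, cell_size = 2) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a positive length (mm)")
  stopifnot_watertight(reference)
  lo <- apply(reference$vertices, 2, min)
  hi <- apply(reference$vertices, 2, max)
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / cell_size - 1e-12)))
  ii <- seq_len(dims[1]) - 1L; jj <- seq_len(dims[2]) - 1L; kk <- seq_len(dims[3]) - 1L
  centers <- cbind(rep(ii, times = dims[2] * dims[3]),
                   rep(rep(jj, each = dims[1]), times = dims[3]),
                   rep(kk, each = dims[1] * dims[2]))
  centers <- sweep((centers + 0.5) * cell_size, 2, lo, "+")
  interior <- array(points_in_mesh(centers, reference), dim = dims)
  structure(list(cell_size = cell_size, origin = lo, dims = dims,
                 interior_mask = interior),
            class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("cell_grid: %d x %d x %d cells of %.3g mm, %d interior\n",
              x$dims[1], x$dims[2], x$dims[3], x$cell_size,
              sum(x$interior_mask)))
  invisible(x)
}

#' Aggregate a registered BMD cloud onto the cell grid
#'
#' Bins each point into the half-open cell containing it and averages the BMD
#' values per interior cell. Points falling outside the grid or into
#' non-interior cells are counted as out-of-grid and excluded from the map;
#' interior cells containing no point are flagged missing (`NA`), distinct
#' from zero.
#'
#' @param cloud a [bmd_point_cloud()] in reference space.
#' @param grid a [cell_grid()][build_cell_grid].
#' @return An object of class `bmd_map` with `mean` and `count` arrays over
#'   the grid, plus `out_of_grid` (number of excluded points) and `grid`.
#' @export
aggregate_bmd <- function(cloud, grid) {
  stopifnot(inherits(cloud, "bmd_point_cloud"), inherits(grid, "cell_grid"))
  dims <- grid$dims
  counts <- array(0L, dim = dims)
  sums <- array(0, dim = dims)
  n <- nrow(cloud$points)
  out_of_grid <- 0L
  if (n > 0) {
    idx <- floor(sweep(cloud$points, 2, grid$origin) / grid$cell_size)
    in_grid <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
      idx[, 2] >= 0 & idx[, 2] < dims[2] &
      idx[, 3] >= 0 & idx[, 3] < dims[3]
    lin <- idx[in_grid, 1] + dims[1] * (idx[in_grid, 2] + dims[2] * idx[in_grid, 3]) + 1
    interior <- grid$interior_mask[lin]
    lin <- lin[interior]
    vals <- cloud$values[in_grid][interior]
    out_of_grid <- n - length(lin)
    if (length(lin)) {
      tab_n <- tapply(rep(1L, length(lin)), lin, sum)
      tab_s <- tapply(vals, lin, sum)
      where <- as.integer(names(tab_n))
      counts[where] <- as.integer(tab_n)
      sums[where] <- as.numeric(tab_s)
    }
  }
  means <- array(NA_real_, dim = dims)
  occ <- counts > 0
  means[occ] <- sums[occ] / counts[occ]
  structure(list(mean = means, count = counts, out_of_grid = out_of_grid,
                 total_points = n, grid = grid),
            class = "bmd_map")
}

#' @export
print.bmd_map <- function(x, ...) {
  occ <- sum(x$count > 0)
  cat(sprintf("bmd_map: %d occupied cells (of %d interior), %d voxels binned, %d out of grid\n",
              occ, sum(x$grid$interior_mask), sum(x$count), x$out_of_grid))
  invisible(x)
}

# 0-based cell index triples and centre coordinates for all interior cells
interior_cell_table <- function(grid) {
  dims <- grid$dims
  which_in <- which(grid$interior_mask)
  k <- (which_in - 1L) %/% (dims[1] * dims[2])
  j <- ((which_in - 1L) %/% dims[1]) %% dims[2]
  i <- (which_in - 1L) %% dims[1]
  data.frame(i = i, j = j, k = k,
             x = grid$origin[1] + (i + 0.5) * grid$cell_size,
             y = grid$origin[2] + (j + 0.5) * grid$cell_size,
             z = grid$origin[3] + (k + 0.5) * grid$cell_size,
             linear = which_in)
}

#' Write a BMD map to CSV
#'
#' One row per interior cell: 0-based cell index triple, cell-centre
#' coordinates (mm, reference space), mean BMD (mg/cc; `NA` for empty cells)
#' and voxel count. Optionally also exports the cell grid as a volume.
#'
#' @param map a [aggregate_bmd()] result.
#' @param path output CSV path.
#' @param volume_path optional `.nii`/`.mhd` path for a volumetric export of
#'   the cell grid (empty cells are NaN).
#' @return `path`, invisibly.
#' @export
write_bmd_map <- function(map, path, volume_path = NULL) {
  stopifnot(inherits(map, "bmd_map"))
  tab <- interior_cell_table(map$grid)
  tab$bmd_mgcc <- map$mean[tab$linear]
  tab$n_voxels <- map$count[tab$linear]
  tab$linear <- NULL
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(volume_path)) {
    vol <- ct_volume(ifelse(is.na(map$mean), NaN, map$mean),
                     spacing = rep(map$grid$cell_size, 3),
                     origin = map$grid$origin + map$grid$cell_size / 2,
                     units = "mg/cc")
    write_volume(vol, volume_path)
  }
  invisible(path)
}

#' Read a BMD map table written by [write_bmd_map()]
#' @param path CSV path.
#' @param grid the [cell_grid()][build_cell_grid] the map was written on.
#' @return a `bmd_map` (its `out_of_grid`/`total_points` reflect the table only).
#' @export
read_bmd_map <- function(path, grid) {
  tab <- read.csv(path)
  dims <- grid$dims
  means <- array(NA_real_, dim = dims)
  counts <- array(0L, dim = dims)
  lin <- tab$i + dims[1] * (tab$j + dims[2] * tab$k) + 1
  means[lin] <- tab$bmd_mgcc
  counts[lin] <- tab$n_voxels
  structure(list(mean = means, count = counts, out_of_grid = NA_integer_,
                 total_points = sum(tab$n_voxels), grid = grid),
            class = "bmd_map")
}
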