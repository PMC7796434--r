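#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the registration and mapping pipeline.
#'
#' @param cell_size isotropic cell side (mm) of the reference BMD grid.
#' @param icp_stiffness decreasing schedule of TPS regularization values used
#'   by the nonrigid ICP step (unitless; larger is stiffer).
#' @param icp_max_inner maximum accepted update iterations per stiffness level.
#' @param icp_tol mean per-vertex displacement (mm) below which a stiffness
#'   level is considered converged.
#' @param icp_control_points number of control points for per-iteration TPS
#'   updates (uniform subsample of the moving vertices).
#' @param distill_control_points control-pair count for the final warp
#'   distilled into a single thin-plate spline (farthest-point subsample).
#' @param tps_regularization regularization of the distilled warp.
#' @param rotation_search_resolution coarse grid step (degrees) for the
#'   femoral axial-rotation search.
#' @param seed integer seed for any stochastic component.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cell_size = 2,
                       icp_stiffness = c(100, 10, 1, 0.1, 0.01),
                       icp_max_inner = 10L,
                       icp_tol = 1e-3,
                       icp_control_points = 500L,
                       distill_control_points = 1000L,
                       tps_regularization = 0,
                       rotation_search_resolution = 1,
                       seed = 1L) {
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  if (!length(icp_stiffness)) stop("icp_stiffness schedule must be non-empty")
  if (any(icp_stiffness < 0)) stop("icp_stiffness must be nonnegative")
  if (tps_regularization < 0) stop("tps_regularization must be nonnegative")
  if (rotation_search_resolution <= 0) stop("rotation_search_resolution must be > 0")
  structure(list(cell_size = cell_size,
                 icp_stiffness = as.numeric(icp_stiffness),
                 icp_max_inner = as.integer(icp_max_inner),
                 icp_tol = icp_tol,
                 icp_control_points = as.integer(icp_control_points),
                 distill_control_points = as.integer(distill_control_points),
                 tps_regularization = tps_regularization,
                 rotation_search_resolution = rotation_search_resolution,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys mirror the arguments of [run_config()].
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
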