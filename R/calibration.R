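#' Calibration-phantom rod sample
#'
#' Mean attenuation measured in a region of interest inside one rod of a solid
#' calcium-hydroxyapatite reference phantom, with the rod's known equivalent
#' density.
#' @param mean_hu mean attenuation (HU) of the rod ROI.
#' @param known_density nominal rod density (mg/cc), nonnegative.
#' @param n_voxels number of voxels in the ROI (>= 1).
#' @return An object of class `phantom_sample`.
#' @export
phantom_sample <- function(mean_hu, known_density, n_voxels = 1L) {
  if (!is.finite(mean_hu)) stop("mean_hu must be finite")
  if (!is.finite(known_density) || known_density < 0)
    stop("known_density must be nonnegative")
  if (n_voxels < 1) stop("n_voxels must be >= 1")
  structure(list(mean_hu = mean_hu, known_density = known_density,
                 n_voxels = as.integer(n_voxels)),
            class = "phantom_sample")
}

#' Fit a linear HU-to-BMD calibration
#'
#' Ordinary least squares of known rod density (mg/cc) on mean rod
#' attenuation (HU): `density = slope * HU + intercept`. This is the standard
#' QCT calibration for a multi-rod solid phantom.
#'
#' @param samples list of [phantom_sample()] objects (>= 2 distinct HU values).
#' @return An object of class `calibration_model` with `slope` (mg/cc per HU),
#'   `intercept` (mg/cc) and `r_squared`.
#' @export
fit_calibration <- function(samples) {
  if (inherits(samples, "phantom_sample")) samples <- list(samples)
  stopifnot(all(vapply(samples, inherits, logical(1), "phantom_sample")))
  hu <- vapply(samples, `[[`, numeric(1), "mean_hu")
  dens <- vapply(samples, `[[`, numeric(1), "known_density")
  if (length(unique(hu)) < 2)
    stop("calibration needs >= 2 samples with distinct mean HU")
  if (sd(hu) < 1e-12) stop("degenerate zero-variance HU values")
  fit <- stats::lm(dens ~ hu)
  co <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dens - mean(dens))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (!is.finite(co[2]) || co[2] == 0) stop("calibration slope is degenerate")
  structure(list(slope = co[2], intercept = co[1], r_squared = r2,
                 n_samples = length(samples)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: BMD = %.6g * HU + %.6g mg/cc (R^2 = %.5f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_samples))
  invisible(x)
}

#' Convert a HU volume to volumetric BMD
#'
#' Applies the calibration line voxel-wise; geometry metadata is unchanged.
#' @param volume a [ct_volume()] in HU.
#' @param model a `calibration_model` from [fit_calibration()].
#' @return a [ct_volume()] with `units = "mg/cc"`.
#' @export
apply_calibration <- function(volume, model) {
  stopifnot(inherits(volume, "ct_volume"), inherits(model, "calibration_model"))
  if (!is.finite(model$slope) || model$slope == 0) stop("invalid calibration model")
  volume$voxels <- model$slope * volume$voxels + model$intercept
  volume$units <- "mg/cc"
  volume
}

#' Read phantom rod samples from CSV
#' @param path CSV with columns `rod_id, mean_hu, known_density_mgcc, n_voxels`.
#' @return list of [phantom_sample()].
#' @export
read_phantom_samples <- function(path) {
  tab <- read.csv(path)
  need <- c("mean_hu", "known_density_mgcc", "n_voxels")
  if (!all(need %in% names(tab)))
    stop("samples CSV must have columns: rod_id, ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    phantom_sample(tab$mean_hu[i], tab$known_density_mgcc[i], tab$n_voxels[i]))
}

#' Write or read a calibration model as YAML
#' @param model a `calibration_model`.
#' @param path YAML path.
#' @return `path` / the model.
#' @export
write_calibration <- function(model, path) {
  yaml::write_yaml(list(slope = model$slope, intercept = model$intercept,
                        r_squared = model$r_squared, n_samples = model$n_samples),
                   path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  v <- yaml::read_yaml(path)
  structure(list(slope = v$slope, intercept = v$intercept,
                 r_squared = v$r_squared, n_samples = v$n_samples %||% NA_integer_),
            class = "calibration_model")
}
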