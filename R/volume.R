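#' CT scalar volume
#'
#' A 3D scalar grid (HU before calibration, mg/cc after) with its geometry:
#' voxel spacing, world origin, and an orthonormal direction matrix. The world
#' position of the voxel centre at 0-based index `(i, j, k)` is
#' `origin + axes %*% (c(i, j, k) * spacing)` (mm).
#'
#' @param voxels 3D numeric array.
#' @param spacing positive length-3 vector (mm).
#' @param origin length-3 vector (mm), world position of voxel (0,0,0).
#' @param axes 3x3 orthonormal direction matrix with determinant +1.
#' @param units `"HU"` or `"mg/cc"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), axes = diag(3),
                      units = "HU") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive lengths (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) stop("origin must be a finite 3-vector")
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3, 3))) stop("axes must be 3x3")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("axes must be orthonormal (within 1e-6)")
  if (det(axes) < 0) stop("axes must be right-handed (det +1)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axes = unname(axes), units = units),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, units %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  invisible(x)
}

# 4x4 voxel-index (0-based) to world affine
volume_affine <- function(vol) {
  m <- diag(4)
  m[1:3, 1:3] <- vol$axes %*% diag(vol$spacing)
  m[1:3, 4] <- vol$origin
  m
}

#' World coordinates of all voxel centres
#' @param vol a [ct_volume()].
#' @return n x 3 matrix in the order of `as.vector(vol$voxels)` (column-major).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$voxels)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  sweep(idx %*% diag(vol$spacing) %*% t(vol$axes), 2, vol$origin, "+")
}

#' Read a CT volume
#'
#' NIfTI (`.nii`, `.nii.gz`) via RNifti, or MetaImage (`.mhd` + `.raw`).
#' Spacing, origin and direction are recovered from the file's affine.
#' @param path file path.
#' @return a [ct_volume()] in HU.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nii", "gz")) {
    img <- RNifti::readNifti(path)
    aff <- unname(structure(RNifti::xform(img), code = NULL))
    voxels <- array(as.numeric(img), dim = dim(img))
    M <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(M^2))
    axes <- M %*% diag(1 / spacing)
    if (max(abs(crossprod(axes) - diag(3))) > 1e-4)
      stop("volume direction matrix is not orthonormal")
    ct_volume(voxels, spacing, aff[1:3, 4], axes)
  } else if (ext == "mhd") {
    read_metaimage(path)
  } else stop("unsupported volume format: .", ext)
}

#' Write a CT volume
#'
#' NIfTI via RNifti (sform/qform carry the full affine) or MetaImage.
#' @param vol a [ct_volume()].
#' @param path output path (`.nii`, `.nii.gz`, or `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nii", "gz")) {
    img <- RNifti::asNifti(structure(vol$voxels, pixdim = vol$spacing),
                           datatype = "double")
    aff <- volume_affine(vol)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (ext == "mhd") {
    write_metaimage(vol, path)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

# MetaImage: plain-text .mhd header plus a raw little-endian data file.
read_metaimage <- function(path) {
  hdr <- readLines(path, warn = FALSE)
  kv <- list()
  for (h in hdr) {
    parts <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- function(k) {
    if (is.null(kv[[k]])) stop("MetaImage header missing ", k)
    kv[[k]]
  }
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (!is.null(kv$Offset)) as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  axes <- if (!is.null(kv$TransformMatrix))
    matrix(as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]]), 3, 3) else diag(3)
  etype <- need("ElementType")
  sz <- switch(etype, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
               stop("unsupported ElementType ", etype))
  datafile <- file.path(dirname(path), need("ElementDataFile"))
  n <- prod(dims)
  con <- file(datafile, "rb")
  on.exit(close(con))
  vals <- if (etype == "MET_SHORT")
    readBin(con, integer(), n = n, size = 2L, signed = TRUE, endian = "little")
  else readBin(con, numeric(), n = n, size = sz, endian = "little")
  ct_volume(array(as.numeric(vals), dim = dims), spacing, origin, axes)
}

write_metaimage <- function(vol, path) {
  d <- dim(vol$voxels)
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("TransformMatrix =", paste(sprintf("%.17g", vol$axes), collapse = " ")),
           paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
           paste("ElementSpacing =", paste(sprintf("%.17g", vol$spacing), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$voxels), con, size = 8L, endian = "little")
  invisible(path)
}
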