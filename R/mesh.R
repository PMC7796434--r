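#' Labeled triangular bone surface
#'
#' Container for a segmented bone surface in scanner millimetre coordinates
#' (right-handed patient frame). The `subchondral_mask` marks the vertices of
#' the subchondral bone area, the anchor patch for registration.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices (triangles).
#' @param subchondral_mask logical vector, one entry per vertex.
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"left"` or `"right"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, subchondral_mask = NULL,
                         bone = c("femur", "tibia"),
                         side = c("right", "left")) {
  bone <- match.arg(bone)
  side <- match.arg(side)
  vertices <- as_points3(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix (triangles)")
  storage.mode(faces) <- "integer"
  faces <- unname(faces)
  nv <- nrow(vertices)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nv))
    stop("faces index vertices outside 1..", nv)
  if (is.null(subchondral_mask)) subchondral_mask <- rep(FALSE, nv)
  subchondral_mask <- as.logical(subchondral_mask)
  if (length(subchondral_mask) != nv)
    stop("subchondral_mask must have one entry per vertex (", nv, "), got ",
         length(subchondral_mask))
  if (anyNA(subchondral_mask)) stop("subchondral_mask contains NA")
  structure(list(vertices = vertices, faces = faces,
                 subchondral_mask = subchondral_mask,
                 bone = bone, side = side),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %s (%s), %d vertices, %d faces, %d subchondral\n",
              x$bone, x$side, nrow(x$vertices), nrow(x$faces),
              sum(x$subchondral_mask)))
  invisible(x)
}

# edge audit: a closed 2-manifold triangle mesh has every edge in exactly 2 faces
#' Test whether a mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces. Required for
#' interior (point-in-mesh) tests.
#' @param mesh a [surface_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

stopifnot_watertight <- function(mesh) {
  if (!is_watertight(mesh))
    stop("mesh is not watertight (an edge is not shared by exactly 2 faces)")
  invisible(mesh)
}

#' Mirror a mesh across the sagittal plane
#'
#' Flips the x (medio-lateral) coordinate and reverses the face winding so the
#' surface orientation is preserved. Used to bring left knees into the
#' package's right-knee convention.
#' @param mesh a [surface_mesh()].
#' @return the mirrored mesh, relabelled as the opposite side.
#' @export
mirror_mesh <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh$side <- if (mesh$side == "left") "right" else "left"
  mesh
}

#' Anatomical anchor points
#'
#' Femur anchors: trochlear notch and the medial/lateral epicondyles. Tibia
#' anchor: the longitudinal (shaft) axis as a unit vector. All in mm.
#' @param trochlear_notch,medial_epicondyle,lateral_epicondyle 3-vectors (femur).
#' @param longitudinal_axis unit 3-vector (tibia).
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(trochlear_notch = NULL, medial_epicondyle = NULL,
                       lateral_epicondyle = NULL, longitudinal_axis = NULL) {
  chk <- function(p, nm) {
    if (is.null(p)) return(NULL)
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p))) stop(nm, " must be a finite 3-vector")
    p
  }
  la <- chk(longitudinal_axis, "longitudinal_axis")
  if (!is.null(la)) la <- unit3(la)
  structure(list(trochlear_notch = chk(trochlear_notch, "trochlear_notch"),
                 medial_epicondyle = chk(medial_epicondyle, "medial_epicondyle"),
                 lateral_epicondyle = chk(lateral_epicondyle, "lateral_epicondyle"),
                 longitudinal_axis = la),
            class = "anchor_set")
}

#' Mirror anchors across the sagittal plane
#' @param anchors an [anchor_set()].
#' @return the mirrored anchor set.
#' @export
mirror_anchors <- function(anchors) {
  flip <- function(p) if (is.null(p)) NULL else p * c(-1, 1, 1)
  anchor_set(trochlear_notch = flip(anchors$trochlear_notch),
             medial_epicondyle = flip(anchors$medial_epicondyle),
             lateral_epicondyle = flip(anchors$lateral_epicondyle),
             longitudinal_axis = flip(anchors$longitudinal_axis))
}

#' Read a labeled bone surface mesh
#'
#' Supports ascii PLY (with a per-vertex `subchondral` property) and ascii STL.
#' STL carries no vertex attributes, so labels come from a sidecar plain-text
#' file (`<path>.labels`, or `labels=` argument) listing 1-based subchondral
#' vertex indices, one per line. STL facets are welded into shared vertices.
#' Left knees are mirrored across the sagittal plane on load so that all
#' registration runs in a right-knee convention.
#'
#' @param path file path (`.ply` or `.stl`).
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"left"` or `"right"`.
#' @param labels optional path to a sidecar subchondral index list.
#' @param mirror_left mirror left knees on load (default `TRUE`).
#' @return a [surface_mesh()]; vertex order is preserved from the file.
#' @export
read_mesh <- function(path, bone = c("femur", "tibia"),
                      side = c("right", "left"), labels = NULL,
                      mirror_left = TRUE) {
  bone <- match.arg(bone)
  side <- match.arg(side)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    parsed <- read_ply(path)
  } else if (ext == "stl") {
    parsed <- read_stl(path)
  } else stop("unsupported mesh format: .", ext)
  mask <- parsed$subchondral
  sidecar <- labels %||% paste0(path, ".labels")
  if (is.null(mask) && file.exists(sidecar)) {
    idx <- scan(sidecar, what = integer(), quiet = TRUE)
    if (length(idx) && (min(idx) < 1L || max(idx) > nrow(parsed$vertices)))
      stop("sidecar label indices out of range")
    mask <- rep(FALSE, nrow(parsed$vertices))
    mask[idx] <- TRUE
  }
  mesh <- surface_mesh(parsed$vertices, parsed$faces, mask, bone, side)
  if (side == "left" && mirror_left) mesh <- mirror_mesh(mesh)
  mesh
}

#' Write a bone surface mesh
#'
#' Ascii PLY with a `uchar subchondral` vertex property, or ascii STL plus a
#' sidecar `<path>.labels` index list.
#' @param mesh a [surface_mesh()].
#' @param path output path (`.ply` or `.stl`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    write_ply(mesh, path)
  } else if (ext == "stl") {
    write_stl(mesh, path)
    idx <- which(mesh$subchondral_mask)
    writeLines(as.character(idx), paste0(path, ".labels"))
  } else stop("unsupported mesh format: .", ext)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr))) stop("only ascii PLY is supported")
  nv <- nf <- NA_integer_
  vprops <- character()
  cur <- ""
  for (h in hdr) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nv <- as.integer(tok[3])
      if (cur == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  if (is.na(nv) || is.na(nf)) stop("PLY header missing vertex/face elements")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY body")
  vtab <- do.call(rbind, lapply(body[seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (ncol(vtab) != length(vprops)) stop("PLY vertex row/property mismatch")
  colnames(vtab) <- vprops
  if (!all(c("x", "y", "z") %in% vprops)) stop("PLY lacks x/y/z vertex properties")
  vertices <- vtab[, c("x", "y", "z"), drop = FALSE]
  subch <- if ("subchondral" %in% vprops) vtab[, "subchondral"] > 0 else NULL
  ftab <- lapply(body[nv + seq_len(nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  counts <- vapply(ftab, function(r) r[1], integer(1))
  if (any(counts != 3L)) stop("non-triangular faces in PLY")
  faces <- do.call(rbind, lapply(ftab, function(r) r[2:4])) + 1L
  list(vertices = vertices, faces = faces, subchondral = subch)
}

write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z",
               "property uchar subchondral",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vl <- sprintf("%.17g %.17g %.17g %d", mesh$vertices[, 1], mesh$vertices[, 2],
                mesh$vertices[, 3], as.integer(mesh$subchondral_mask))
  writeLines(vl, con)
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(fl, con)
  invisible(path)
}

read_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(lines) || !startsWith(lines[1], "solid"))
    stop("only ascii STL is supported")
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) %% 3L != 0L) stop("malformed STL: vertex count not divisible by 3")
  coords <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(l, "\\s+")[[1]][2:4])))
  # weld duplicated facet vertices (exact textual coordinates match)
  key <- apply(coords, 1, paste, collapse = " ")
  uid <- match(key, unique(key))
  vertices <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces, subchondral = NULL)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid kneemap", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
           (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
           (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "outer loop",
                 sprintf("vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
                 sprintf("vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
                 sprintf("vertex %.17g %.17g %.17g", c3[1], c3[2], c3[3]),
                 "endloop", "endfacet"), con)
  }
  writeLines("endsolid kneemap", con)
  invisible(path)
}

#' Points strictly inside a watertight mesh
#'
#' Ray-parity interior test (a point is inside when a ray from it crosses the
#' surface an odd number of times); rays that graze an edge are retried along
#' a different direction.
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight [surface_mesh()].
#' @return logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh) {
  stopifnot_watertight(mesh)
  points <- as_points3(points)
  .cpp_points_in_mesh(points, mesh$vertices, mesh$faces - 1L)
}

#' Closest points on a mesh surface
#'
#' Exact point-to-surface projection onto the triangles of a mesh.
#' @param points n x 3 matrix (mm).
#' @param mesh a [surface_mesh()] (need not be watertight).
#' @param faces optional subset of face indices to project onto.
#' @return list with `points` (projections), `distance`, `face`.
#' @export
closest_on_mesh <- function(points, mesh, faces = NULL) {
  points <- as_points3(points)
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  if (nrow(f) == 0) stop("mesh has no faces to project onto")
  .cpp_closest_point_on_mesh(points, mesh$vertices, f - 1L)
}

# faces all of whose vertices are subchondral (the anchor patch triangles)
subchondral_faces <- function(mesh) {
  m <- mesh$subchondral_mask
  which(m[mesh$faces[, 1]] & m[mesh$faces[, 2]] & m[mesh$faces[, 3]])
}
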