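#' Construct and validate a triangle surface mesh
#'
#' The basic geometric container of the package: a triangle surface in
#' millimetres, as produced by desktop digitization of dental casts. Vertices
#' are an `n x 3` numeric matrix, faces an `m x 3` integer matrix of 1-based
#' vertex indices. Per-vertex unit normals are computed (area-weighted from
#' incident faces) when not supplied.
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z in mm).
#' @param faces integer matrix, one triangle per row (1-based vertex indices).
#' @param normals optional numeric matrix of per-vertex unit normals.
#' @param validate validate invariants (finite coordinates, indices in range,
#'   no zero-area faces)? Default `TRUE`.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `normals`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  mesh <- structure(list(vertices = vertices, faces = faces, normals = normals),
                    class = "surface_mesh")
  if (validate) mesh <- validate_mesh(mesh)
  if (is.null(mesh$normals)) mesh$normals <- vertex_normals(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bounding box diagonal %.2f mm\n",
              sqrt(sum((bb[2, ] - bb[1, ])^2))))
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks that all coordinates are finite, all face indices are in range, and
#' drops degenerate (zero-area) faces. Errors on non-finite coordinates or
#' out-of-range indices; an empty mesh is a validation error.
#'
#' @param mesh a `surface_mesh`.
#' @param area_tol faces with area below this (mm^2) are dropped.
#' @return The validated mesh.
#' @export
validate_mesh <- function(mesh, area_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L || nrow(f) == 0L) stop("empty geometry is not a valid mesh")
  if (!all(is.finite(v))) stop("mesh vertices contain non-finite coordinates")
  if (anyNA(f) || min(f) < 1L || max(f) > nrow(v))
    stop("face indices out of range")
  a <- face_areas(v, f)
  keep <- a > area_tol
  if (!all(keep)) {
    f <- f[keep, , drop = FALSE]
    if (nrow(f) == 0L) stop("all faces degenerate")
    mesh$faces <- f
    mesh$normals <- NULL
  }
  mesh
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

face_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cx  # length = 2 * area, i.e. area-weighted
}

#' Per-vertex unit normals (area-weighted average of incident face normals)
#' @param mesh a `surface_mesh`.
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(v, f)
  out <- matrix(0, nrow(v), 3)
  idx <- c(f[, 1], f[, 2], f[, 3])
  for (d in 1:3) {
    s <- rowsum(rep(fn[, d], 3), idx)
    out[as.integer(rownames(s)), d] <- s[, 1]
  }
  len <- sqrt(rowSums(out^2))
  len[len < 1e-30] <- 1
  out / len
}

#' Read an STL file (binary or ASCII)
#'
#' Reads either STL dialect, merges duplicate vertices within 1e-6 mm (STL
#' stores each facet's corners independently), recomputes per-vertex normals
#' from the face winding, and validates the result. Units are taken to be
#' millimetres (dental metrology convention); there is no unit autodetection.
#'
#' @param path path to an STL file.
#' @return A validated `surface_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  fsize <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  is_binary <- FALSE
  nfaces <- 0L
  if (fsize >= 84) {
    readBin(con, "raw", 80L)  # header, ignored
    nfaces <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    is_binary <- length(nfaces) == 1L && !is.na(nfaces) && nfaces >= 0L &&
      fsize == 84 + 50 * as.numeric(nfaces)
  }
  if (is_binary) {
    tri <- read_stl_binary(con, nfaces)
  } else {
    tri <- read_stl_ascii(path)
  }
  if (nrow(tri) == 0L) stop("empty geometry in STL file: ", path)
  mesh_from_triangle_soup(tri)
}

read_stl_binary <- function(con, nfaces) {
  rec <- readBin(con, "raw", 50L * nfaces)
  if (length(rec) < 50L * nfaces) stop("truncated binary STL body")
  rec <- matrix(rec, nrow = 50L)
  coords <- readBin(as.vector(rec[13:48, , drop = FALSE]), "numeric",
                    9L * nfaces, size = 4L, endian = "little")
  m <- matrix(coords, ncol = 9L, byrow = TRUE)
  # facet-major triangle soup: rows v1, v2, v3 of facet 1, then facet 2, ...
  matrix(t(m), ncol = 3L, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("unreadable STL file (not binary, no ASCII vertex records): ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  m <- do.call(rbind, nums)
  if (anyNA(m)) stop("malformed ASCII STL vertex line")
  m
}

# triangle soup (3 consecutive rows per facet) -> surface_mesh with duplicate
# vertices merged at `tol`
mesh_from_triangle_soup <- function(tri, tol = 1e-6) {
  key <- paste(round(tri[, 1] / tol), round(tri[, 2] / tol), round(tri[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  verts <- tri[first, , drop = FALSE]
  faces <- matrix(map, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write an STL file
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param dialect `"binary"` (default, standard 80-byte-header layout) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  mesh <- validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(v, f)
  len <- sqrt(rowSums(fn^2)); len[len < 1e-30] <- 1
  fn <- fn / len
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("recess3d binary STL", width = -80)), con)
    writeBin(nrow(f), con, size = 4L, endian = "little")
    rec <- t(cbind(fn, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))
    body <- writeBin(as.vector(rec), raw(), size = 4L, endian = "little")
    body <- matrix(body, nrow = 48L)
    out <- rbind(body, matrix(as.raw(0L), 2L, ncol(body)))
    writeBin(as.vector(out), con)
  } else {
    lines <- c("solid recess3d")
    tri <- cbind(fn, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    fmt <- function(p) paste(formatC(p, format = "g", digits = 17), collapse = " ")
    body <- apply(tri, 1, function(r) {
      paste0("  facet normal ", fmt(r[1:3]), "\n    outer loop\n",
             "      vertex ", fmt(r[4:6]), "\n",
             "      vertex ", fmt(r[7:9]), "\n",
             "      vertex ", fmt(r[10:12]), "\n",
             "    endloop\n  endfacet")
    })
    writeLines(c(lines, body, "endsolid recess3d"), path)
  }
  invisible(path)
}

mesh_bbox <- function(mesh) apply(mesh$vertices, 2, range)
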