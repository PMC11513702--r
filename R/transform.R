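#' Rigid transforms
#'
#' A rigid transform maps points `p` (rows) to `p %*% t(R) + t`. Rotations are
#' constrained to be proper (orthonormal, determinant +1); no scaling is ever
#' estimated or applied, since both timepoints are metric scans.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid transform needs a 3x3 rotation and length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("matrix is not a proper rotation (orthonormal, det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation %.4f mm\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to a mesh, a point matrix, or a single point
#'
#' Lengths and angles are preserved (isometry). Mesh normals are rotated.
#'
#' @param x a `surface_mesh`, an `n x 3` matrix, or a length-3 point.
#' @param transform a `rigid_transform`.
#' @return Object of the same kind as `x`.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- transform$rotation
  tr <- transform$translation
  if (inherits(x, "surface_mesh")) {
    x$vertices <- x$vertices %*% t(R) + rep(tr, each = nrow(x$vertices))
    if (!is.null(x$normals)) x$normals <- x$normals %*% t(R)
    return(x)
  }
  if (is.matrix(x)) return(x %*% t(R) + rep(tr, each = nrow(x)))
  if (length(x) == 3L) return(as.numeric(R %*% x + tr))
  stop("cannot transform object of class ", paste(class(x), collapse = "/"))
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

#' Rotation angle of a rotation matrix, in degrees
#' @param rotation 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(rotation) {
  ct <- (sum(diag(rotation)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Rotation about an axis
#' @param axis rotation axis (any length-3 vector, normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return A `rigid_transform` with zero translation.
#' @export
rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  rigid_transform(diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K))
}

#' Serialise / deserialise a rigid transform as 12 numbers
#'
#' Plain-text format: one number per line, the row-major 3x3 rotation followed
#' by the translation vector, as written by the `register` pipeline stage.
#'
#' @param transform a `rigid_transform`.
#' @param path output (input) file path.
#' @return `write_transform`: `path` invisibly; `read_transform`: the
#'   `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  vals <- c(t(transform$rotation), transform$translation)
  writeLines(formatC(vals, format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  vals <- as.numeric(readLines(path, warn = FALSE))
  if (length(vals) != 12L || anyNA(vals))
    stop("transform file must contain exactly 12 numbers")
  R <- matrix(vals[1:9], 3, 3, byrow = TRUE)
  # guard against text round-off
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, vals[10:12])
}
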