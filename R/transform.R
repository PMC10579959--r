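#' Construct a rigid transform
#'
#' A rotation plus translation, the only transform class the alignment
#' permits (no scaling, no deformation). The rotation is validated to be a
#' proper orthonormal matrix (determinant +1) to within 1e-9.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector in mm.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' compose_transforms(t1, invert_transform(t1))  # identity
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("`rotation` must be 3 x 3")
  if (length(translation) != 3L) stop("`translation` must have length 3")
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("transform entries must be finite")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthonormal to within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be proper (determinant +1); got det = ", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_to_axis_angle(x$rotation)
  cat(sprintf("Rigid transform: rotation %.3f deg about (%.3f, %.3f, %.3f), translation (%.3f, %.3f, %.3f) mm\n",
              aa$angle * 180 / pi, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `first`, then `second`:
#' `x -> R2 (R1 x + t1) + t2`.
#'
#' @param second,first `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"), inherits(first, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

# map an n x 3 coordinate matrix through a rigid transform
transform_points <- function(points, transform) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Apply a rigid transform to a surface
#'
#' Maps every vertex `v` to `R v + t`; faces and labels are untouched, so all
#' pairwise inter-vertex distances are preserved (rigidity).
#'
#' @param surface a [labeled_surface()].
#' @param transform a [rigid_transform()].
#' @return The transformed [labeled_surface()].
#' @export
apply_transform <- function(surface, transform) {
  stopifnot(inherits(surface, "labeled_surface"), inherits(transform, "rigid_transform"))
  surface$vertices <- transform_points(surface$vertices, transform)
  surface
}

#' Convert to/from a 4 x 4 homogeneous matrix
#'
#' @param transform a [rigid_transform()].
#' @return `as_homogeneous()`: a 4 x 4 matrix; `transform_from_homogeneous()`:
#'   a [rigid_transform()].
#' @export
as_homogeneous <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
}

#' @rdname as_homogeneous
#' @param mat a 4 x 4 homogeneous rigid transform matrix.
#' @export
transform_from_homogeneous <- function(mat) {
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(4L, 4L))) stop("expected a 4 x 4 matrix")
  if (max(abs(mat[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row must be (0, 0, 0, 1)")
  rigid_transform(mat[1:3, 1:3], mat[1:3, 4])
}

#' Read/write a rigid transform as plain text
#'
#' The on-disk format is the 4 x 4 homogeneous matrix, row-major, whitespace
#' delimited, millimetre translation, `#` comment lines ignored.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns a [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  m <- as_homogeneous(transform)
  lines <- c("# rigid transform, 4x4 homogeneous, row-major, mm",
             apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != 4L) stop("expected 4 matrix rows in ", path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  if (any(lengths(vals) != 4L) || any(!is.finite(unlist(vals))))
    stop("malformed transform file ", path)
  transform_from_homogeneous(do.call(rbind, vals))
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula. The inverse, [rotation_to_axis_angle()], returns the
#' angle in `[0, pi]` and a unit axis (arbitrary for the identity).
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @rdname rotation_from_axis_angle
#' @param rotation a 3 x 3 rotation matrix.
#' @return For `rotation_to_axis_angle()`: a list with `axis` and `angle`.
#' @export
rotation_to_axis_angle <- function(rotation) {
  tr <- sum(diag(rotation))
  angle <- acos(min(1, max(-1, (tr - 1) / 2)))
  if (angle < 1e-12) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(angle - pi) < 1e-6) {
    # near pi the antisymmetric part vanishes; take axis from R + I
    M <- (rotation + diag(3)) / 2
    axis <- unit(sqrt(pmax(diag(M), 0)) *
                   sign(c(1, ifelse(M[1, 2] >= 0, 1, -1), ifelse(M[1, 3] >= 0, 1, -1))))
    return(list(axis = axis, angle = angle))
  }
  w <- c(rotation[3, 2] - rotation[2, 3],
         rotation[1, 3] - rotation[3, 1],
         rotation[2, 1] - rotation[1, 2]) / (2 * sin(angle))
  list(axis = unit(w), angle = angle)
}

# Nearest rotation matrix (Frobenius) via polar decomposition. Keeps the
# linearized ICP update a proper rotation at every iteration.
project_to_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  R
}
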