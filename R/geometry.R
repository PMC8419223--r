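# Coordinate conventions (used throughout the package):
#   image plane  z = 0, principal point at the origin,
#   projection center F = (0, 0, z_F) with z_F > 0,
#   scene points typically at z < 0 (in front of the camera, behind the
#   image plane).  Projection itself is general and does not enforce the
#   scene-side convention.

#' Perspective camera
#'
#' A pinhole camera with its image plane at `z = 0`, principal point at the
#' origin, and center of projection at `(0, 0, z_F)`.  `z_F = Inf` flags the
#' orthographic limit.
#'
#' @param z_F Distance of the projection center from the image plane
#'   (arbitrary length units, `> 0`), or `Inf` for an orthographic camera.
#' @return An object of class `"camera"`.
#' @examples
#' cam <- camera(z_F = 2)
#' project_perspective(cbind(1, 0, -2), cam)
#' @export
camera <- function(z_F) {
  if (!is.numeric(z_F) || length(z_F) != 1L || is.na(z_F) || z_F <= 0) {
    stop("'z_F' must be a single positive number (or Inf for orthographic)")
  }
  structure(list(z_F = z_F, orthographic = is.infinite(z_F)),
            class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  if (x$orthographic) {
    cat("Orthographic camera (z_F = Inf), image plane z = 0\n")
  } else {
    cat(sprintf("Perspective camera: F = (0, 0, %g), image plane z = 0\n",
                x$z_F))
  }
  invisible(x)
}

as_points3d <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) %% 3L != 0L) stop("points must have 3 columns (x, y, z)")
    points <- matrix(points, ncol = 3L, byrow = TRUE)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)")
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  points
}

as_points2d <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) %% 2L != 0L) stop("image points must have 2 columns (x, y)")
    points <- matrix(points, ncol = 2L, byrow = TRUE)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("image points must have 2 columns (x, y)")
  if (any(!is.finite(points))) stop("image point coordinates must be finite")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}

#' Perspective projection onto the image plane
#'
#' Projects 3D points through the center of projection `F = (0, 0, z_F)` onto
#' the image plane `z = 0`: the image of `(X, Y, Z)` is
#' `(X z_F / (z_F - Z), Y z_F / (z_F - Z))`.
#'
#' @param points Numeric matrix with columns `x, y, z` (one row per point).
#' @param cam A [camera()]. An orthographic camera delegates to
#'   [project_orthographic()].
#' @return Matrix of image points with columns `x, y`.
#' @export
project_perspective <- function(points, cam) {
  stopifnot(inherits(cam, "camera"))
  if (cam$orthographic) return(project_orthographic(points))
  points <- as_points3d(points)
  if (nrow(points) == 0L) return(as_points2d(matrix(numeric(0), ncol = 2L)))
  denom <- cam$z_F - points[, 3L]
  if (any(abs(denom) < .Machine$double.eps * max(1, abs(cam$z_F)))) {
    stop("point(s) with Z = z_F: projecting ray is parallel to the image plane")
  }
  scale <- cam$z_F / denom
  as_points2d(cbind(points[, 1L] * scale, points[, 2L] * scale))
}

#' Orthographic projection onto the image plane
#'
#' The `z_F -> Inf` limit of [project_perspective()]: coordinates `(X, Y)`
#' are dropped onto `z = 0` unchanged.
#'
#' @inheritParams project_perspective
#' @return Matrix of image points with columns `x, y`.
#' @export
project_orthographic <- function(points) {
  points <- as_points3d(points)
  as_points2d(points[, 1:2, drop = FALSE])
}

#' 3D plane in Hessian normal form
#'
#' Plane `a x + b y + c z + d = 0` with unit normal `(a, b, c)`.  Non-unit
#' coefficient vectors are normalized with a warning.
#'
#' @param a,b,c,d Plane coefficients; `(a, b, c)` must be non-zero.
#' @return Object of class `"plane3d"` (named numeric vector).
#' @export
plane3d <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v))) stop("plane coefficients must be finite")
  nrm <- sqrt(sum(v[1:3]^2))
  if (nrm < .Machine$double.eps) stop("plane normal must be non-zero")
  if (abs(nrm - 1) > 1e-12) {
    warning("plane coefficients not normalized; normalizing")
    v <- v / nrm
  }
  structure(v, class = "plane3d")
}

#' Signed distance of points from a plane
#'
#' @param points Matrix of 3D points.
#' @param plane A [plane3d()].
#' @return Numeric vector of signed distances.
#' @export
plane_distance <- function(points, plane) {
  stopifnot(inherits(plane, "plane3d"))
  points <- as_points3d(points)
  drop(points %*% plane[1:3]) + plane[4L]
}

#' Mirror reflection about a plane
#'
#' Maps each point to its mirror image about `plane`; an involution
#' (applying it twice restores the input).
#'
#' @inheritParams plane_distance
#' @return Matrix of reflected points.
#' @export
mirror_reflect <- function(points, plane) {
  stopifnot(inherits(plane, "plane3d"))
  points <- as_points3d(points)
  d <- plane_distance(points, plane)
  points - 2 * outer(d, unclass(plane)[1:3])
}

#' Rigid motion (rotation + translation)
#'
#' @param rotation Orthonormal 3x3 matrix with determinant +1.
#' @param translation Numeric length-3 translation vector.
#' @param tol Orthonormality tolerance.
#' @return Object of class `c("rigid_motion", "transform3d")`.
#' @export
rigid_motion <- function(rotation = diag(3), translation = c(0, 0, 0),
                         tol = 1e-9) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("rotation matrix is not orthonormal within tolerance")
  }
  if (det(rotation) < 0) stop("rotation must have determinant +1")
  stopifnot(length(translation) == 3L, all(is.finite(translation)))
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = 1),
            class = c("rigid_motion", "transform3d"))
}

#' Similarity transform (rigid motion + uniform scaling)
#'
#' @inheritParams rigid_motion
#' @param scale Uniform scale factor `s > 0`.
#' @return Object of class `c("similarity_transform", "transform3d")`.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1, tol = 1e-9) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("'scale' must be a single positive number")
  }
  tr <- rigid_motion(rotation, translation, tol)
  tr$scale <- scale
  class(tr) <- c("similarity_transform", "transform3d")
  tr
}

#' Apply a rigid or similarity transform to points
#'
#' Rigid motions preserve all pairwise distances; similarity transforms scale
#' distances by `s` and preserve angles.
#'
#' @param points Matrix of 3D points.
#' @param transform A [rigid_motion()] or [similarity_transform()].
#' @return Matrix of transformed points.
#' @export
apply_transform <- function(points, transform) {
  stopifnot(inherits(transform, "transform3d"))
  points <- as_points3d(points)
  out <- transform$scale * points %*% t(transform$rotation)
  as_points3d(sweep(out, 2L, transform$translation, "+"))
}

#' Rotation matrix about a coordinate axis or arbitrary axis
#'
#' @param angle Rotation angle in radians.
#' @param axis Either `"x"`, `"y"`, `"z"`, or a numeric length-3 axis vector.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angle, axis = "z") {
  if (is.character(axis)) {
    axis <- match.arg(axis, c("x", "y", "z"))
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random rotation matrix (uniform on SO(3))
#'
#' Drawn via QR decomposition of a Gaussian matrix, sign-corrected to
#' determinant +1.  Uses the current RNG state.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Read and write 3D point lists as CSV
#'
#' CSV files use a header row `x,y,z` (image point files `x,y`), comma
#' separator and dot decimal mark.
#'
#' @param path File path.
#' @return `read_points_csv()` returns a point matrix.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("x", "y", "z") %in% names(df))) {
    as_points3d(as.matrix(df[, c("x", "y", "z")]))
  } else if (all(c("x", "y") %in% names(df))) {
    as_points2d(as.matrix(df[, c("x", "y")]))
  } else {
    stop("CSV must have columns x,y,z (3D) or x,y (image points)")
  }
}

#' @rdname read_points_csv
#' @param points Point matrix (3 columns for 3D, 2 for image points).
#' @export
write_points_csv <- function(points, path) {
  points <- if (ncol(as.matrix(points)) == 3L) as_points3d(points) else
    as_points2d(points)
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
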