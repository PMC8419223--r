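# Synthetic scene and image generators.  These define the study conditions
# used throughout the tests and the model-observer experiment: random
# mirror-symmetric 16-vertex objects in front of the camera, their perspective
# images, and Gaussian image-coordinate noise.

#' Random mirror-symmetric 3D point pairs
#'
#' Generates `n_pairs` mirror pairs about a symmetry plane of canonical form
#' `-(x_v/z_F) x + z + d_c = 0`, optionally rotated by a random angle about
#' the optical axis.  Midpoints are drawn on the plane in front of the camera
#' (`z < 0`) and pairs are offset symmetrically along the plane normal, so
#' the configuration is exactly mirror-symmetric and its image chords share
#' the vanishing point `(x_v, 0)` (pre-rotation).  Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param n_pairs Number of mirror pairs.
#' @param cam A finite-`z_F` [camera()].
#' @param x_v Vanishing point abscissa; default drawn uniformly from
#'   `±[1.5, 4] z_F`.
#' @param d_c Symmetry-plane offset; default drawn uniformly from `[2.5, 3.5]`.
#' @param rotate Apply a random rotation about the optical axis (keeps the
#'   object symmetric while making the image frame general).
#' @return List with matrices `P`, `Q`, `M`, the `plane` ([plane3d()]),
#'   scalars `d_c` and `x_v` (canonical frame), and the applied
#'   `rotation_angle`.
#' @export
random_symmetric_pairs <- function(n_pairs = 8L, cam = camera(2),
                                   x_v = NULL, d_c = NULL, rotate = TRUE) {
  stopifnot(inherits(cam, "camera"), !cam$orthographic, n_pairs >= 2L)
  if (is.null(x_v)) {
    x_v <- sample(c(-1, 1), 1L) * stats::runif(1L, 1.5, 4) * cam$z_F
  }
  if (is.null(d_c)) d_c <- stats::runif(1L, 2.5, 3.5)
  n <- c(-x_v / cam$z_F, 0, 1)
  n_hat <- n / sqrt(sum(n^2))
  x_M <- stats::runif(n_pairs, -0.3, 0.3)
  y_M <- stats::runif(n_pairs, -1, 1)
  z_M <- (x_v / cam$z_F) * x_M - d_c
  M <- cbind(x_M, y_M, z_M)
  t_i <- stats::runif(n_pairs, 0.2, 0.8)
  P <- M + t_i %o% n_hat
  Q <- M - t_i %o% n_hat
  angle <- 0
  if (rotate) {
    angle <- stats::runif(1L, 0, 2 * pi)
    Rz <- rotation_matrix(angle, "z")
    P <- P %*% t(Rz); Q <- Q %*% t(Rz); M <- M %*% t(Rz)
    n_hat <- drop(Rz %*% n_hat)
  }
  # canonical plane n . x + d_c = 0 has non-unit |n|; Hessian offset is d_c/|n|
  plane <- plane3d(n_hat[1L], n_hat[2L], n_hat[3L], d_c / sqrt(sum(n^2)))
  list(P = as_points3d(P), Q = as_points3d(Q), M = as_points3d(M),
       plane = plane, d_c = d_c, x_v = x_v, rotation_angle = angle)
}

#' Project a 3D pair set to an image correspondence set
#'
#' Projects `P` and `Q` with the camera and optionally adds isotropic
#' Gaussian image-coordinate noise of standard deviation `sigma` (image
#' units) to every image point.
#'
#' @param shape List with matrices `P` and `Q` (e.g. from
#'   [random_symmetric_pairs()] or [generate_stimulus()]).
#' @param cam A [camera()].
#' @param sigma Image noise standard deviation (0 for noiseless).
#' @return A [correspondences()] object.
#' @export
project_pairs <- function(shape, cam, sigma = 0) {
  p <- project_perspective(shape$P, cam)
  q <- project_perspective(shape$Q, cam)
  if (sigma > 0) {
    p <- p + matrix(stats::rnorm(length(p), sd = sigma), ncol = 2L)
    q <- q + matrix(stats::rnorm(length(q), sd = sigma), ncol = 2L)
  }
  correspondences(p, q)
}
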