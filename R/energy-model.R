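# The symmetry-constrained cost functional
#   E(X) = ||A(X) - Y|| + lambda ||P(X)||
# where A is perspective projection, Y the observed image correspondences and
# P(X) the departure of the candidate 3D pair set from exact mirror symmetry.
# With squared Euclidean norms, minimizing E is the maximum a posteriori
# estimate under Gaussian image noise and a Gaussian symmetry prior with
# lambda = sigma_data^2 / sigma_prior^2.

#' Energy model for symmetry-constrained 3D recovery
#'
#' @param data A [correspondences()] object (the observed image `Y`).
#' @param cam A finite-`z_F` [camera()].
#' @param lambda Non-negative constraint weight.
#' @param norm_order Norm exponent applied to both terms; the default `2`
#'   (squared Euclidean) is the one for which the MAP equivalence holds.
#' @return Object of class `"energy_model"`.
#' @export
energy_model <- function(data, cam, lambda = 1, norm_order = 2) {
  stopifnot(inherits(data, "correspondences"), inherits(cam, "camera"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("'lambda' must be a single non-negative number")
  }
  structure(list(data = data, camera = cam, lambda = lambda,
                 norm_order = norm_order),
            class = "energy_model")
}

as_pair_set <- function(X) {
  if (inherits(X, "recovered_shape")) X <- list(P = X$P, Q = X$Q)
  stopifnot(is.list(X), !is.null(X$P), !is.null(X$Q))
  list(P = as_points3d(X$P), Q = as_points3d(X$Q))
}

norm_term <- function(sq_sum, order) {
  if (order == 2) sq_sum else sq_sum^(order / 2)
}

#' Reprojection residual `||A(X) - Y||`
#'
#' Sum of squared image distances (default norm) between the projected
#' candidate pairs and the observed image pairs.
#'
#' @param X Candidate 3D pair set: list with matrices `P`, `Q` (or a
#'   [recover_shape()] result).
#' @param data A [correspondences()] object with the same number of pairs.
#' @param cam A [camera()].
#' @param norm_order Norm exponent (see [energy_model()]).
#' @return Scalar residual.
#' @export
reprojection_residual <- function(X, data, cam, norm_order = 2) {
  X <- as_pair_set(X)
  stopifnot(inherits(data, "correspondences"))
  if (nrow(X$P) != nrow(data$p)) {
    stop("candidate and data must have the same number of pairs")
  }
  p_hat <- project_perspective(X$P, cam)
  q_hat <- project_perspective(X$Q, cam)
  norm_term(sum((p_hat - data$p)^2) + sum((q_hat - data$q)^2), norm_order)
}

# optimal mirror offset for a fixed unit normal
best_offset <- function(X, n) {
  # reflect(P) = P - 2 (P.n - d) n ; minimizing sum||reflect(P_i) - Q_i||^2
  # over d is quadratic: residual r_i = (I - 2nn')P_i + 2 d n - Q_i
  HP <- X$P - 2 * outer(drop(X$P %*% n), n)
  base <- HP - X$Q
  # d* minimizes sum || base_i + 2 d n ||^2  ->  d* = -sum(base_i . n)/(2N)
  -sum(base %*% n) / (2 * nrow(X$P))
}

asymmetry_for_normal <- function(X, n) {
  d <- best_offset(X, n)
  HP <- X$P - 2 * outer(drop(X$P %*% n) - d, n)
  sum((HP - X$Q)^2)
}

#' Asymmetry penalty `||P(X)||`
#'
#' Departure of a candidate pair set from exact mirror symmetry: the minimum
#' over mirror planes of the sum of squared distances between the reflected
#' `P_i` and `Q_i`.  Exactly zero iff `X` is mirror-symmetric with the given
#' pairing.  The plane is found by optimizing the unit normal (spherical
#' parameterization, quasi-Newton, initialized from the principal direction
#' of the chords `Q_i - P_i`); the offset has a closed form.
#'
#' @param X Candidate 3D pair set (list with `P`, `Q`).
#' @param norm_order Norm exponent (see [energy_model()]).
#' @param return_plane Also return the minimizing plane.
#' @param restarts Run extra optimizer restarts from axis-aligned normals
#'   (recommended for strongly asymmetric clouds; the principal-direction
#'   start alone suffices near symmetric configurations).
#' @return Scalar penalty, or (with `return_plane`) a list with `penalty` and
#'   `plane`.
#' @export
asymmetry_penalty <- function(X, norm_order = 2, return_plane = FALSE,
                              restarts = TRUE) {
  X <- as_pair_set(X)
  n_pairs <- nrow(X$P)
  if (n_pairs < 3L) {
    warning("fewer than 3 pairs: mirror plane underdetermined")
  }
  D <- X$Q - X$P
  # init: principal direction of the chords
  sv <- svd(D)
  n0 <- sv$v[, 1L]
  to_angles <- function(n) c(acos(max(-1, min(1, n[3L]))),
                             atan2(n[2L], n[1L]))
  from_angles <- function(a) c(sin(a[1L]) * cos(a[2L]),
                               sin(a[1L]) * sin(a[2L]), cos(a[1L]))
  obj <- function(a) asymmetry_for_normal(X, from_angles(a))
  fit <- stats::optim(to_angles(n0), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  if (restarts && fit$value > 1e-18 * sum(D^2)) {
    for (a0 in list(c(pi / 2, 0), c(pi / 2, pi / 2), c(0.01, 0))) {
      alt <- stats::optim(a0, obj, method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 200))
      if (alt$value < fit$value) fit <- alt
    }
  }
  n_best <- from_angles(fit$par)
  pen <- norm_term(max(0, fit$value), norm_order)
  if (!return_plane) return(pen)
  d <- best_offset(X, n_best)
  list(penalty = pen,
       plane = plane3d(n_best[1L], n_best[2L], n_best[3L], -d))
}

#' Evaluate the energy functional
#'
#' `E(X) = ||A(X) - Y|| + lambda ||P(X)||`: reprojection residual plus
#' weighted asymmetry penalty.  Non-negative; zero iff `X` reprojects exactly
#' onto the data and is exactly mirror-symmetric.
#'
#' @param X Candidate 3D pair set.
#' @param model An [energy_model()].
#' @return Scalar energy.
#' @export
energy <- function(X, model) {
  stopifnot(inherits(model, "energy_model"))
  reprojection_residual(X, model$data, model$camera, model$norm_order) +
    model$lambda * asymmetry_penalty(X, model$norm_order)
}

#' Minimize the energy functional
#'
#' Quasi-Newton (BFGS, analytic gradients for the squared norms) minimization
#' of [energy()] over the candidate pair set (`6 n` coordinates), started
#' from the closed-form recovery of the (possibly noisy) correspondences,
#' with seeded random restarts to mitigate local minima.  On noiseless data
#' the minimizer coincides with the closed-form recovery.
#'
#' Monocular perspective leaves a one-parameter gauge freedom: scaling the
#' scene about the projection center is a similarity transform (it preserves
#' shape) that leaves every reprojection unchanged while shrinking the
#' absolute asymmetry penalty, so the unconstrained functional has a
#' degenerate collapse direction.  The minimizer therefore fixes this gauge:
#' every candidate is rescaled about the projection center to the
#' initializer's mean distance from it before the energy is evaluated
#' (exactly the same family that the closed form indexes by `d_c`).
#'
#' @param model An [energy_model()].
#' @param init Optional initial candidate (list with `P`, `Q` or a
#'   [recover_shape()] result); default is the closed-form recovery with
#'   `force = TRUE`.
#' @param n_restarts Number of jittered restarts (in addition to the main
#'   start).
#' @param maxit Iteration budget per start.
#' @param tol Relative tolerance on `E`.
#' @return List of class `"energy_fit"`: `X` (the minimizer), `value`,
#'   `reprojection`, `penalty`, `convergence` flag, `iterations`.
#' @export
minimize_energy <- function(model, init = NULL, n_restarts = 3L,
                            maxit = 500L, tol = 1e-10) {
  stopifnot(inherits(model, "energy_model"))
  if (is.null(init)) {
    init <- suppressWarnings(
      recover_shape(model$data, model$camera, force = TRUE))
  }
  init <- as_pair_set(init)
  n <- nrow(init$P)
  pack <- function(X) c(X$P, X$Q)
  unpack <- function(par) list(P = matrix(par[seq_len(3 * n)], n, 3L),
                               Q = matrix(par[3 * n + seq_len(3 * n)], n, 3L))
  # gauge: mean distance of the points from the projection center F
  Fc <- c(0, 0, model$camera$z_F)
  rho <- function(A) mean(sqrt(rowSums(sweep(A, 2L, Fc)^2)))
  rho0 <- rho(rbind(init$P, init$Q))
  fix_gauge <- function(X) {
    A <- rbind(X$P, X$Q)
    s <- rho0 / rho(A)
    A <- sweep(s * sweep(A, 2L, Fc), 2L, Fc, "+")
    list(P = A[seq_len(n), , drop = FALSE],
         Q = A[n + seq_len(n), , drop = FALSE], s = s)
  }
  # inner mirror-plane fit, warm-started across objective evaluations
  plane_cache <- new.env(parent = emptyenv())
  plane_cache$angles <- NULL
  from_angles <- function(a) c(sin(a[1L]) * cos(a[2L]),
                               sin(a[1L]) * sin(a[2L]), cos(a[1L]))
  fit_plane <- function(X) {
    a0 <- plane_cache$angles
    if (is.null(a0)) {
      n0 <- svd(X$Q - X$P)$v[, 1L]
      a0 <- c(acos(max(-1, min(1, n0[3L]))), atan2(n0[2L], n0[1L]))
    }
    fit <- stats::optim(a0, function(a) asymmetry_for_normal(X, from_angles(a)),
                        method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 100))
    plane_cache$angles <- fit$par
    list(value = max(0, fit$value), n = from_angles(fit$par))
  }
  obj <- function(par) {
    X <- fix_gauge(unpack(par))
    tryCatch(
      reprojection_residual(X, model$data, model$camera, model$norm_order) +
        model$lambda * norm_term(fit_plane(X)$value, model$norm_order),
      error = function(e) 1e10)
  }
  # analytic gradient for the squared-Euclidean norms; the asymmetry term
  # uses the envelope theorem (the inner mirror plane is optimal, so its
  # dependence on X contributes nothing to first order)
  grad <- if (model$norm_order == 2) function(par) {
    Xraw <- unpack(par)
    gfix <- fix_gauge(Xraw)
    X <- list(P = gfix$P, Q = gfix$Q)
    cam <- model$camera
    g <- function(pts3, obs) {
      s <- cam$z_F / (cam$z_F - pts3[, 3L])
      hat <- cbind(pts3[, 1L] * s, pts3[, 2L] * s)
      r <- hat - obs
      cbind(2 * r[, 1L] * s, 2 * r[, 2L] * s,
            2 * (r[, 1L] * pts3[, 1L] + r[, 2L] * pts3[, 2L]) * s^2 / cam$z_F)
    }
    gP <- g(X$P, model$data$p)
    gQ <- g(X$Q, model$data$q)
    pl <- fit_plane(X)
    n_hat <- pl$n
    d <- best_offset(X, n_hat)
    r <- (X$P - 2 * outer(drop(X$P %*% n_hat) - d, n_hat)) - X$Q
    HR <- r - 2 * outer(drop(r %*% n_hat), n_hat)
    gP <- gP + model$lambda * 2 * HR
    gQ <- gQ - model$lambda * 2 * r
    # pull the gradient back through the gauge map X~ = F + s (X - F),
    # s = rho0 / rho(X):  d/dX_i = s g_i + (ds/dX_i) sum_j (X_j - F) . g_j
    gt <- rbind(gP, gQ)
    A <- sweep(rbind(Xraw$P, Xraw$Q), 2L, Fc)
    len <- sqrt(rowSums(A^2))
    u <- A / len
    s <- gfix$s
    inner <- sum(sweep(rbind(X$P, X$Q), 2L, Fc) * gt) / s  # sum (X_j - F).g_j
    corr <- -(s / (rho0 / s)) / (2 * n) * inner
    gfull <- s * gt + corr * u
    c(gfull[seq_len(n), ], gfull[n + seq_len(n), ])
  } else NULL
  run <- function(par0) {
    stats::optim(par0, obj, gr = grad, method = "BFGS",
                 control = list(reltol = tol, maxit = maxit))
  }
  best <- run(pack(init))
  scale <- max(abs(pack(init)), 1)
  for (r in seq_len(n_restarts)) {
    par0 <- pack(init) + stats::rnorm(6 * n, sd = 0.01 * scale)
    cand <- run(par0)
    if (cand$value < best$value) best <- cand
  }
  X_best <- unpack(best$par)
  structure(list(
    X = lapply(X_best, as_points3d),
    value = best$value,
    reprojection = reprojection_residual(X_best, model$data, model$camera,
                                         model$norm_order),
    penalty = asymmetry_penalty(X_best, model$norm_order),
    convergence = best$convergence == 0L,
    iterations = best$counts[["function"]]
  ), class = "energy_fit")
}

#' @export
print.energy_fit <- function(x, ...) {
  cat(sprintf(paste0("Energy minimization: E = %.6g (reprojection %.6g,",
                     " penalty %.6g), %s in %d evaluations\n"),
              x$value, x$reprojection, x$penalty,
              if (x$convergence) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Log-posterior of a candidate shape (MAP reading of the energy)
#'
#' Up to an additive constant,
#' `log p(X | Y) = -||A(X) - Y||^2 / (2 sigma_data^2)
#'                 - ||P(X)||^2 / (2 sigma_prior^2)`,
#' where the squared norms are the squared-Euclidean reprojection residual
#' and asymmetry penalty.  Its argmax equals the argmin of the energy with
#' `lambda = sigma_data^2 / sigma_prior^2`.
#'
#' @param X Candidate 3D pair set.
#' @param model An [energy_model()] (its `lambda` is ignored here).
#' @param sigma_data Image noise standard deviation (`> 0`).
#' @param sigma_prior Symmetry prior standard deviation (`> 0`).
#' @return Log-posterior up to a constant.
#' @export
map_log_posterior <- function(X, model, sigma_data, sigma_prior) {
  stopifnot(inherits(model, "energy_model"))
  if (sigma_data <= 0 || sigma_prior <= 0) {
    stop("sigma_data and sigma_prior must be positive")
  }
  rep2 <- reprojection_residual(X, model$data, model$camera, norm_order = 2)
  pen2 <- asymmetry_penalty(X, norm_order = 2)
  -rep2 / (2 * sigma_data^2) - pen2 / (2 * sigma_prior^2)
}

#' Variance-matched constraint weight
#'
#' `lambda = sigma_data^2 / sigma_prior^2`, the weight for which the energy
#' minimum is the MAP estimate.
#'
#' @inheritParams map_log_posterior
#' @return Scalar `lambda`.
#' @export
lambda_from_sigmas <- function(sigma_data, sigma_prior) {
  if (sigma_data <= 0 || sigma_prior <= 0) {
    stop("sigma_data and sigma_prior must be positive")
  }
  sigma_data^2 / sigma_prior^2
}
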