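# Numerical least-action suite: action quadrature, Euler-Lagrange residuals,
# stationarity of the action under endpoint-fixed perturbations, and the
# Noether pairing between symmetries of the Lagrangian and conserved
# quantities (coordinate independence -> momentum, time independence ->
# energy).  All derivatives of L are central finite differences; no symbolic
# algebra is used.

# Relative step for central differences of L.  1e-5 balances truncation
# against the cancellation noise that the subsequent time differentiation of
# the conjugate momentum amplifies by 1/(2 dt) on fine grids.
FD_REL_STEP <- 1e-5

#' Lagrangian system
#'
#' Either a general Lagrangian `L(q, qdot, t)` on `m` generalized
#' coordinates, or the mechanical form `L = (1/2) m |qdot|^2 - V(q)` given a
#' mass and a potential.
#'
#' @param L Function `(q, qdot, t) -> scalar`; `q` and `qdot` are numeric
#'   vectors of length `dim`.  Omit to use the mechanical form.
#' @param dim Number of generalized coordinates.
#' @param mass Particle mass (mechanical form).
#' @param potential Function `q -> scalar` potential `V(q)` (mechanical form).
#' @return Object of class `"lagrangian_system"`.
#' @examples
#' osc <- lagrangian_system(mass = 1, potential = function(q) 0.5 * q^2)
#' @export
lagrangian_system <- function(L = NULL, dim = 1L, mass = NULL,
                              potential = NULL) {
  if (is.null(L)) {
    if (is.null(mass) || is.null(potential)) {
      stop("supply either L or both mass and potential")
    }
    force(mass); force(potential)
    L <- function(q, qdot, t) 0.5 * mass * sum(qdot^2) - potential(q)
  }
  structure(list(L = L, dim = as.integer(dim), mass = mass,
                 potential = potential),
            class = "lagrangian_system")
}

#' Sampled trajectory on a uniform time grid
#'
#' @param time Strictly increasing, uniform time grid (`n >= 3`).
#' @param q Matrix (`n` rows) or vector of generalized coordinates.
#' @param qdot Optional matrix/vector of velocities; if omitted, velocities
#'   are computed by second-order finite differences (central in the
#'   interior, one-sided at the ends).
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(time, q, qdot = NULL) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 3L) stop("need at least 3 time samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1L])) > 1e-9 * dt[1L]) {
    stop("time grid must be uniform")
  }
  q <- as.matrix(q)
  if (nrow(q) != n) stop("q must have one row per time sample")
  if (is.null(qdot)) {
    qdot <- apply(q, 2L, fd_derivative, dt = dt[1L])
    qdot <- matrix(qdot, nrow = n)
  } else {
    qdot <- as.matrix(qdot)
    if (nrow(qdot) != n) stop("qdot must have one row per time sample")
  }
  structure(list(time = time, q = q, qdot = qdot, dt = dt[1L], n = n),
            class = "trajectory")
}

# second-order finite differences on a uniform grid
fd_derivative <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1L] <- (-3 * x[1L] + 4 * x[2L] - x[3L]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1L] + x[n - 2L]) / (2 * dt)
  d
}

eval_L <- function(system, traj) {
  vapply(seq_len(traj$n), function(i) {
    system$L(traj$q[i, ], traj$qdot[i, ], traj$time[i])
  }, numeric(1))
}

#' Action of a trajectory
#'
#' Trapezoid quadrature of the Lagrangian along the trajectory,
#' `S = integral of L(q, qdot, t) dt`; converges at `O(dt^2)`.
#'
#' @param system A [lagrangian_system()].
#' @param traj A [trajectory()].
#' @return Scalar action `S`.
#' @export
action <- function(system, traj) {
  stopifnot(inherits(system, "lagrangian_system"), inherits(traj, "trajectory"))
  Lv <- eval_L(system, traj)
  traj$dt * (sum(Lv) - (Lv[1L] + Lv[traj$n]) / 2)
}

# partial derivatives of L by central differences with relative step
dL_dq <- function(system, q, qdot, t, j) {
  h <- FD_REL_STEP * max(1, abs(q[j]))
  qp <- q; qm <- q; qp[j] <- q[j] + h; qm[j] <- q[j] - h
  (system$L(qp, qdot, t) - system$L(qm, qdot, t)) / (2 * h)
}

dL_dqdot <- function(system, q, qdot, t, j) {
  h <- FD_REL_STEP * max(1, abs(qdot[j]))
  vp <- qdot; vm <- qdot; vp[j] <- qdot[j] + h; vm[j] <- qdot[j] - h
  (system$L(q, vp, t) - system$L(q, vm, t)) / (2 * h)
}

#' Euler-Lagrange residual along a trajectory
#'
#' Samples `dL/dq_j - d/dt (dL/dqdot_j)` on the interior of the grid
#' (central differences for both the partials of `L` and the time derivative
#' of the conjugate momentum).  Near zero on true trajectories of the
#' dynamics; systematically non-zero otherwise.
#'
#' @param system A [lagrangian_system()].
#' @param traj A [trajectory()] with `n >= 5`.
#' @return Matrix (interior samples x coordinates) of residuals, with the
#'   interior times as the `"time"` attribute.
#' @export
el_residual <- function(system, traj) {
  stopifnot(inherits(system, "lagrangian_system"), inherits(traj, "trajectory"))
  if (traj$n < 5L) stop("need at least 5 samples for central differences")
  m <- ncol(traj$q)
  p <- sapply(seq_len(m), function(j) {
    vapply(seq_len(traj$n), function(i) {
      dL_dqdot(system, traj$q[i, ], traj$qdot[i, ], traj$time[i], j)
    }, numeric(1))
  })
  p <- matrix(p, nrow = traj$n)
  interior <- 2:(traj$n - 1L)
  res <- sapply(seq_len(m), function(j) {
    dpdt <- (p[interior + 1L, j] - p[interior - 1L, j]) / (2 * traj$dt)
    dLdq <- vapply(interior, function(i) {
      dL_dq(system, traj$q[i, ], traj$qdot[i, ], traj$time[i], j)
    }, numeric(1))
    dLdq - dpdt
  })
  res <- matrix(res, nrow = length(interior))
  attr(res, "time") <- traj$time[interior]
  res
}

#' First-order stationarity of the action under perturbations
#'
#' Evaluates `S(eps)` for trajectories `q + eps * eta` over an `eps` grid and
#' fits a quadratic: a true trajectory has `|dS/deps| ~ 0` at `eps = 0`, and
#' the sign of the curvature classifies the stationary point.  Perturbations
#' must vanish at both endpoints.
#'
#' @param system A [lagrangian_system()].
#' @param traj A [trajectory()].
#' @param perturbation Function `t -> numeric(dim)` (or a vector function for
#'   1D) with `perturbation(t1) = perturbation(t2) = 0`.
#' @param eps Grid of perturbation amplitudes (symmetric around 0).
#' @return List with `dS_deps` (slope at 0), `curvature`, `stationary`
#'   (logical, relative to `tol * |S|`), `kind` (`"minimum"`, `"maximum"`,
#'   `"saddle/flat"`), `S0`, and the fitted values.
#' @param tol Relative stationarity tolerance (`|dS/deps| < tol * |S|`).
#' @export
stationarity_check <- function(system, traj, perturbation,
                               eps = seq(-0.05, 0.05, length.out = 11),
                               tol = 1e-6) {
  stopifnot(inherits(system, "lagrangian_system"), inherits(traj, "trajectory"))
  m <- ncol(traj$q)
  eta <- t(vapply(traj$time, function(t) {
    val <- perturbation(t)
    if (length(val) != m) stop("perturbation must return length-dim values")
    as.numeric(val)
  }, numeric(m)))
  eta <- matrix(eta, nrow = traj$n)
  end_mag <- max(abs(eta[c(1L, traj$n), ]))
  if (end_mag > 1e-12 * max(1, max(abs(eta)))) {
    stop("perturbation must vanish at both endpoints")
  }
  S_eps <- vapply(eps, function(e) {
    action(system, trajectory(traj$time, traj$q + e * eta))
  }, numeric(1))
  fit <- stats::lm(S_eps ~ eps + I(eps^2))
  slope <- unname(stats::coef(fit)[2L])
  curv <- 2 * unname(stats::coef(fit)[3L])
  S0 <- action(system, traj)
  kind <- if (abs(curv) < 1e-10 * max(1, abs(S0))) "saddle/flat"
  else if (curv > 0) "minimum" else "maximum"
  list(dS_deps = slope, curvature = curv,
       stationary = abs(slope) < tol * max(abs(S0), .Machine$double.eps),
       kind = kind, S0 = S0, eps = eps, S_eps = S_eps)
}

#' Conserved quantity along a trajectory (Noether check)
#'
#' Computes the time series of a candidate conserved quantity and its drift
#' (max minus min over the interior grid): conjugate momenta
#' `p_j = dL/dqdot_j` for `kind = "momentum"`, or the energy function
#' `E = sum_j qdot_j p_j - L` for `kind = "energy"`.  By Noether's pairing,
#' the drift vanishes (to grid accuracy) when `L` is independent of the
#' corresponding coordinate, respectively of time.  A non-zero drift is
#' reported, not an error: it simply means the quantity is not conserved.
#'
#' @param system A [lagrangian_system()].
#' @param traj A [trajectory()].
#' @param kind `"momentum"` or `"energy"`.
#' @param coordinate Coordinate index for `kind = "momentum"`.
#' @return List with `series` (interior time series), `drift`
#'   (`max - min`), and `time`.
#' @export
conserved_quantity <- function(system, traj,
                               kind = c("momentum", "energy"),
                               coordinate = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(system, "lagrangian_system"), inherits(traj, "trajectory"))
  interior <- 2:(traj$n - 1L)
  series <- vapply(interior, function(i) {
    q <- traj$q[i, ]; qdot <- traj$qdot[i, ]; t <- traj$time[i]
    if (kind == "momentum") {
      dL_dqdot(system, q, qdot, t, coordinate)
    } else {
      p <- vapply(seq_along(qdot), function(j) {
        dL_dqdot(system, q, qdot, t, j)
      }, numeric(1))
      sum(qdot * p) - system$L(q, qdot, t)
    }
  }, numeric(1))
  list(series = series, drift = max(series) - min(series),
       time = traj$time[interior])
}

#' Integrate the equations of motion of a mechanical system
#'
#' Runge-Kutta integration (via [deSolve::ode()], classical `rk4`) of
#' `m qddot = -grad V(q)` for a [lagrangian_system()] given in mechanical
#' form, returning a [trajectory()] on a uniform grid.
#'
#' @param system A [lagrangian_system()] with `mass` and `potential`.
#' @param q0,qdot0 Initial coordinates and velocities.
#' @param t1,t2 Time interval.
#' @param n Number of grid samples.
#' @return A [trajectory()] (with integrated velocities attached).
#' @export
integrate_trajectory <- function(system, q0, qdot0, t1 = 0, t2 = 1,
                                 n = 1001L) {
  stopifnot(inherits(system, "lagrangian_system"))
  if (is.null(system$mass) || is.null(system$potential)) {
    stop("integration requires the mechanical form (mass + potential)")
  }
  m <- length(q0)
  gradV <- function(q) {
    vapply(seq_len(m), function(j) {
      h <- FD_REL_STEP * max(1, abs(q[j]))
      qp <- q; qm <- q; qp[j] <- q[j] + h; qm[j] <- q[j] - h
      (system$potential(qp) - system$potential(qm)) / (2 * h)
    }, numeric(1))
  }
  deriv <- function(t, y, parms) {
    q <- y[seq_len(m)]; v <- y[m + seq_len(m)]
    list(c(v, -gradV(q) / system$mass))
  }
  times <- seq(t1, t2, length.out = n)
  sol <- deSolve::ode(y = c(q0, qdot0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  trajectory(times, sol[, 1L + seq_len(m), drop = FALSE],
             sol[, 1L + m + seq_len(m), drop = FALSE])
}
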