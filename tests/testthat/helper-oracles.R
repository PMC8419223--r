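# Independent oracles used across the test files.  These deliberately avoid
# the code paths they are checking.

# Ray-intersection oracle for mirror-pair depths: given one image pair in the
# canonical frame (vanishing point on the x-axis), the camera and the
# symmetry-plane offset, solve for the two points directly from the
# projecting-ray parameterization and the mirror constraint:
#   P(t) = (t p_x, t p_y, z_F (1 - t)),  Q(s) likewise,
#   Q - P = mu * n  with n = (-x_v/z_F, 0, 1),
#   midpoint on plane  -(x_v/z_F) x + z + d_c = 0.
# Four linear equations in (t, s, mu), solved by least squares; for
# consistent input the residual vanishes and the solution is exact.
oracle_pair_depths <- function(p, q, x_v, z_F, d_c) {
  n <- c(-x_v / z_F, 0, 1)
  # unknowns (t, s, mu)
  A <- rbind(
    c(-p[1], q[1], -n[1]),
    c(-p[2], q[2], -n[2]),
    c(z_F, -z_F, -n[3]),
    c(-(x_v / z_F) * p[1] / 2 - z_F / 2,
      -(x_v / z_F) * q[1] / 2 - z_F / 2, 0))
  b <- c(0, 0, 0, -d_c - z_F)
  sol <- qr.solve(A, b)
  t <- unname(sol[1]); s <- unname(sol[2])
  p <- unname(p); q <- unname(q)
  list(P = c(t * p[1], t * p[2], z_F * (1 - t)),
       Q = c(s * q[1], s * q[2], z_F * (1 - s)),
       residual = sqrt(sum((A %*% sol - b)^2)))
}

# Brute-force asymmetry plane search on an angular grid (about 10 degrees),
# using only the closed-form offset for a fixed normal.
oracle_asymmetry_grid <- function(P, Q, step_deg = 10) {
  step <- step_deg * pi / 180
  thetas <- seq(0, pi, by = step)
  phis <- seq(0, 2 * pi, by = step)
  best <- Inf
  for (th in thetas) for (ph in phis) {
    n <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    # closed-form optimal offset for this normal
    HP <- P - 2 * outer(drop(P %*% n), n)
    d_opt <- -sum((HP - Q) %*% n) / (2 * nrow(P))
    HPd <- HP + 2 * d_opt * outer(rep(1, nrow(P)), n)
    val <- sum((HPd - Q)^2)
    if (val < best) best <- val
  }
  best
}

# quick generator wrapper used by several files
gen_shape <- function(n_pairs = 8L, z_F = 2, ...) {
  cam <- camera(z_F)
  sh <- random_symmetric_pairs(n_pairs, cam, ...)
  sh$camera <- cam
  sh
}
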