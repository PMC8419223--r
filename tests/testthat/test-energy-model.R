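make_model <- function(seed = 7, sigma = 0, lambda = 1, n = 8) {
  set.seed(seed)
  sh <- gen_shape(n)
  cs <- project_pairs(sh, sh$camera, sigma = sigma)
  list(shape = sh,
       model = energy_model(cs, sh$camera, lambda = lambda))
}

test_that("reprojection residual is zero at truth and along projection rays", {
  mm <- make_model()
  X <- list(P = mm$shape$P, Q = mm$shape$Q)
  expect_equal(reprojection_residual(X, mm$model$data, mm$model$camera), 0)
  # sliding points along their projecting rays leaves the residual at 0
  cam <- mm$model$camera
  slide <- function(A, f) {
    Fc <- matrix(c(0, 0, cam$z_F), nrow(A), 3, byrow = TRUE)
    Fc + f * (A - Fc)
  }
  X2 <- list(P = slide(mm$shape$P, 1.3), Q = slide(mm$shape$Q, 0.6))
  expect_lt(reprojection_residual(X2, mm$model$data, cam), 1e-20)
  # a single image-plane offset of delta contributes delta^2
  delta <- 0.01
  p2 <- mm$model$data$p; p2[1, 1] <- p2[1, 1] + delta
  shifted <- correspondences(p2, mm$model$data$q)
  expect_equal(reprojection_residual(X, shifted, cam), delta^2,
               tolerance = 1e-10)
  expect_error(reprojection_residual(list(P = mm$shape$P[1:3, ],
                                          Q = mm$shape$Q[1:3, ]),
                                     mm$model$data, cam), "same number")
})

test_that("asymmetry penalty vanishes iff the pairing is mirror-symmetric", {
  mm <- make_model()
  X <- list(P = mm$shape$P, Q = mm$shape$Q)
  expect_lt(asymmetry_penalty(X), 1e-20)
  # one displaced point: penalty positive but bounded by its displacement
  eps <- 0.05
  Q2 <- mm$shape$Q; Q2[3, ] <- Q2[3, ] + c(0, 0, eps)
  pen <- asymmetry_penalty(list(P = mm$shape$P, Q = Q2))
  expect_gt(pen, 0)
  expect_lte(pen, eps^2 + 1e-12)
  expect_warning(asymmetry_penalty(list(P = mm$shape$P[1:2, ],
                                        Q = mm$shape$Q[1:2, ])),
                 "underdetermined")
})

test_that("asymmetry penalty matches a 10-degree grid-search oracle", {
  set.seed(23)
  for (i in 1:5) {
    P <- matrix(rnorm(24), ncol = 3)
    Q <- matrix(rnorm(24), ncol = 3)
    pen <- asymmetry_penalty(list(P = P, Q = Q))
    grid <- oracle_asymmetry_grid(P, Q, step_deg = 10)
    expect_lte(pen, grid + 1e-9)          # optimizer at least as good
    expect_lt((grid - pen) / max(grid, 1e-12), 0.35)  # within grid resolution
  }
})

test_that("energy combines the two terms and is monotone in lambda", {
  mm <- make_model(sigma = 0.01)
  rec <- suppressWarnings(recover_shape(mm$model$data, mm$model$camera,
                                        force = TRUE))
  X <- list(P = mm$shape$P, Q = mm$shape$Q)
  e0 <- energy(X, energy_model(mm$model$data, mm$model$camera, lambda = 0))
  expect_equal(e0, reprojection_residual(X, mm$model$data, mm$model$camera))
  lams <- c(0, 0.5, 1, 5)
  es <- vapply(lams, function(l) {
    energy(X, energy_model(mm$model$data, mm$model$camera, lambda = l))
  }, numeric(1))
  expect_true(all(diff(es) >= -1e-12))
  expect_error(energy_model(mm$model$data, mm$model$camera, lambda = -1),
               "non-negative")
  # truth on noiseless data has zero energy
  clean <- make_model()
  expect_lt(energy(list(P = clean$shape$P, Q = clean$shape$Q), clean$model),
            1e-18)
})

test_that("minimizer reproduces the closed form on noiseless data", {
  mm <- make_model()
  fit <- minimize_energy(mm$model, n_restarts = 1)
  rec <- recover_shape(mm$model$data, mm$model$camera)
  expect_lt(max(abs(fit$X$P - rec$P), abs(fit$X$Q - rec$Q)), 1e-6)
  expect_lt(fit$value, 1e-12)
  expect_true(fit$convergence)
})

test_that("lambda extremes drive the minimizer to symmetry or to the data", {
  mm <- make_model(seed = 31, sigma = 0.004)
  # lambda large: essentially exact symmetry
  big <- minimize_energy(energy_model(mm$model$data, mm$model$camera,
                                      lambda = 1e6), n_restarts = 0)
  expect_lt(big$penalty, 1e-8)
  # lambda = 0: reprojection through the noisy points (depths are free)
  zero <- minimize_energy(energy_model(mm$model$data, mm$model$camera,
                                       lambda = 0), n_restarts = 0)
  expect_lt(zero$reprojection, 1e-12)
})

test_that("regularization improves noisy recovery over the raw closed form", {
  # matched lambda = sigma_data^2 / sigma_prior^2; shape error is scored
  # after similarity alignment (monocular recovery has a free scale)
  set.seed(33)
  sh <- gen_shape(8)
  wins <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    cs <- project_pairs(sh, sh$camera, sigma = 0.005)
    lam <- lambda_from_sigmas(0.005, 0.005)
    rec <- suppressWarnings(recover_shape(cs, sh$camera, force = TRUE))
    fit <- minimize_energy(energy_model(cs, sh$camera, lambda = lam),
                           init = rec, n_restarts = 0, maxit = 200)
    truth <- rbind(sh$P, sh$Q)
    e_closed <- procrustes_distance(rbind(rec$P, rec$Q), truth)
    e_energy <- procrustes_distance(rbind(fit$X$P, fit$X$Q), truth)
    if (e_energy < e_closed) wins <- wins + 1L
  }
  expect_gt(wins / n_rep, 0.5)
})

test_that("MAP log-posterior is the negative energy up to scaling", {
  mm <- make_model(seed = 35, sigma = 0.003)
  sigma_d <- 0.003; sigma_p <- 0.01
  lam <- lambda_from_sigmas(sigma_d, sigma_p)
  expect_equal(lam, sigma_d^2 / sigma_p^2)
  model_lam <- energy_model(mm$model$data, mm$model$camera, lambda = lam)
  # 1-parameter family of candidates: truth morphed toward an asymmetric pose
  set.seed(36)
  D <- matrix(rnorm(48, sd = 0.05), 16, 3)
  cand <- function(a) {
    V <- rbind(mm$shape$P, mm$shape$Q) + a * D
    list(P = V[1:8, ], Q = V[9:16, ])
  }
  a_grid <- seq(-1, 1, length.out = 41)
  E <- vapply(a_grid, function(a) energy(cand(a), model_lam), numeric(1))
  LP <- vapply(a_grid, function(a) {
    map_log_posterior(cand(a), mm$model, sigma_d, sigma_p)
  }, numeric(1))
  expect_equal(which.min(E), which.max(LP))
  # ranking of candidates identical under E and -log posterior
  expect_equal(order(E), order(-LP))
  # sigma_prior -> Inf: posterior tends to the likelihood alone
  LP_flat <- vapply(a_grid, function(a) {
    map_log_posterior(cand(a), mm$model, sigma_d, 1e9)
  }, numeric(1))
  lik <- vapply(a_grid, function(a) {
    -reprojection_residual(cand(a), mm$model$data, mm$model$camera) /
      (2 * sigma_d^2)
  }, numeric(1))
  expect_equal(LP_flat, lik, tolerance = 1e-6)
  expect_error(map_log_posterior(cand(0), mm$model, -1, 1), "positive")
})
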