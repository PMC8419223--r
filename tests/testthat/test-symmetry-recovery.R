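test_that("vanishing point estimation recovers a constructed intersection", {
  # two pairs on lines through (3, 0) at distinct angles
  mk <- function(ang, r1, r2) {
    u <- c(cos(ang), sin(ang))
    list(p = c(3, 0) + r1 * u, q = c(3, 0) + r2 * u)
  }
  a <- mk(2.2, 1, 2); b <- mk(2.8, 0.5, 1.5)
  cs <- correspondences(rbind(a$p, b$p), rbind(a$q, b$q))
  vp <- estimate_vanishing_point(cs)
  expect_false(vp$orthographic)
  expect_lt(max(abs(vp$point - c(3, 0))), 1e-10)
  expect_lt(vp$residual, 1e-12)

  # parallel chords: vanishing point at infinity
  csp <- correspondences(rbind(c(0, 0), c(0, 1)), rbind(c(1, 0), c(1, 1)))
  expect_true(estimate_vanishing_point(csp)$orthographic)

  expect_error(estimate_vanishing_point(
    correspondences(rbind(c(0, 0)), rbind(c(1, 1)))), "at least 2")
})

test_that("noisy correspondences give a nearby vanishing point", {
  set.seed(11)
  angs <- seq(0.6, 2.5, length.out = 12)
  p <- t(sapply(angs, function(a) c(3, 0) + 1.0 * c(cos(a), sin(a))))
  q <- t(sapply(angs, function(a) c(3, 0) + 2.5 * c(cos(a), sin(a))))
  err <- replicate(20, {
    cs <- correspondences(p + matrix(rnorm(24, sd = 1e-3), ncol = 2),
                          q + matrix(rnorm(24, sd = 1e-3), ncol = 2))
    vp <- estimate_vanishing_point(cs)
    c(abs(vp$point[1] - 3), abs(vp$point[2]), vp$residual)
  })
  expect_lt(median(err[1, ]), 0.05)
  expect_lt(median(err[2, ]), 0.05)
  # residual reflects the noise scale
  expect_gt(median(err[3, ]), 1e-4)
  expect_lt(median(err[3, ]), 1e-2)
})

test_that("vanishing line follows x_h = -z_F^2 / x_v", {
  expect_equal(vanishing_line(2, camera(2)), -2)
  expect_equal(vanishing_line(-4, camera(2)), 1)
  expect_equal(vanishing_line(1e12, camera(2)), 0, tolerance = 1e-10)
  expect_error(vanishing_line(0, camera(2)), "singular")
})

test_that("midpoint image is the harmonic-mean point on the chord", {
  # equal radii: m coincides with both image points
  m <- midpoint_image(2, 2, pi / 3, 1)
  expect_equal(unname(m), rbind(c(1 + 2 * cos(pi / 3), 2 * sin(pi / 3))))
  # r_psi -> 0: m -> vanishing point
  m0 <- midpoint_image(1, 1e-12, 0.4, 3)
  expect_lt(max(abs(m0 - rbind(c(3, 0)))), 1e-10)
  expect_error(midpoint_image(0, 0, 0.4, 3), "non-zero")
  # AM-HM: m never farther from v than the image midpoint of p, q
  set.seed(12)
  for (i in 1:200) {
    r1 <- runif(1, 0.1, 3); r2 <- runif(1, 0.1, 3); a <- runif(1, 0, 2 * pi)
    h <- sqrt(sum((midpoint_image(r1, r2, a, 0) - c(0, 0))^2))
    expect_lte(h, (r1 + r2) / 2 + 1e-12)
  }
})

test_that("Eq.-(7) midpoint equals the projection of the true 3D midpoint", {
  set.seed(13)
  worst <- 0
  for (i in 1:200) {
    sh <- gen_shape(8, z_F = runif(1, 1, 5), rotate = FALSE)
    cam <- sh$camera
    pol <- mirrorshape:::pair_polar(project_perspective(sh$P, cam),
                                    project_perspective(sh$Q, cam), sh$x_v)
    m_formula <- midpoint_image(pol$r_p, pol$r_q, pol$alpha, sh$x_v)
    m_true <- project_perspective(sh$M, cam)
    worst <- max(worst, max(abs(m_formula - m_true)))
  }
  expect_lt(worst, 1e-10)
})

test_that("closed-form depths agree with the ray-intersection oracle", {
  set.seed(14)
  for (i in 1:50) {
    sh <- gen_shape(6, z_F = runif(1, 1, 4), rotate = FALSE)
    cam <- sh$camera
    p <- project_perspective(sh$P, cam)
    q <- project_perspective(sh$Q, cam)
    pol <- mirrorshape:::pair_polar(p, q, sh$x_v)
    dep <- recover_depths(pol$r_p, pol$r_q, pol$alpha, sh$x_v, cam, sh$d_c)
    for (j in seq_len(nrow(p))) {
      orc <- oracle_pair_depths(p[j, ], q[j, ], sh$x_v, cam$z_F, sh$d_c)
      expect_lt(orc$residual, 1e-8)
      expect_equal(dep$z_phi[j], orc$P[3], tolerance = 1e-8)
      expect_equal(dep$z_psi[j], orc$Q[3], tolerance = 1e-8)
    }
  }
})

test_that("equal image radii give equal depths, and swapping radii swaps them", {
  cam <- camera(2)
  d1 <- recover_depths(1.5, 1.5, 0.7, 3, cam, 1)
  expect_equal(d1$z_phi, d1$z_psi)
  d2 <- recover_depths(1.2, 2.1, 0.7, 3, cam, 1)
  d3 <- recover_depths(2.1, 1.2, 0.7, 3, cam, 1)
  expect_equal(d2$z_phi, d3$z_psi)
  expect_equal(d2$z_psi, d3$z_phi)
})

test_that("midpoint on the vanishing line is rejected", {
  cam <- camera(2)
  x_h <- vanishing_line(1, cam)  # -4
  # radii/angle with x_m = x_v + h cos(alpha) = 1 - 5 = -4 = x_h
  expect_error(recover_depths(5, 5, pi, 1, cam, 1), "vanishing line")
})

test_that("back projection inverts perspective projection", {
  cam <- camera(1)
  expect_equal(unname(back_project(rbind(c(0, 0)), -7, cam)),
               rbind(c(0, 0, -7)))
  expect_equal(unname(back_project(rbind(c(0.5, 0)), -1, cam)),
               rbind(c(1, 0, -1)))
  set.seed(15)
  img <- matrix(rnorm(20), ncol = 2)
  z <- runif(10, -5, -1)
  pts <- back_project(img, z, cam)
  expect_lt(max(abs(project_perspective(pts, cam) - img)), 1e-12)
  expect_error(back_project(rbind(c(1, 1)), 1, cam), "z_F")
})

test_that("full recovery round-trips noiseless symmetric shapes exactly", {
  set.seed(16)
  worst <- 0
  for (i in 1:40) {
    sh <- gen_shape(8, z_F = sample(c(2, 10, 100), 1))
    cs <- project_pairs(sh, sh$camera)
    rec <- recover_shape(cs, sh$camera, d_c = sh$d_c)
    worst <- max(worst, max(abs(rec$P - sh$P)), max(abs(rec$Q - sh$Q)))
    # midpoints coplanar on the recovered symmetry plane
    expect_lt(max(abs(plane_distance(rec$M, rec$plane))), 1e-9)
    # reflecting P about the plane gives Q
    expect_lt(max(abs(mirror_reflect(rec$P, rec$plane) - rec$Q)), 1e-8)
    # reprojection reproduces the input image
    expect_lt(max(abs(project_perspective(rec$P, sh$camera) - cs$p)), 1e-9)
  }
  expect_lt(worst, 1e-8)
})

test_that("varying d_c sweeps a similarity family of shapes", {
  set.seed(17)
  sh <- gen_shape(8)
  cs <- project_pairs(sh, sh$camera)
  recs <- lapply(c(0.5, 1, 2), function(dc) {
    recover_shape(cs, sh$camera, d_c = dc)
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(procrustes_distance(rbind(recs[[i]]$P, recs[[i]]$Q),
                                  rbind(recs[[j]]$P, recs[[j]]$Q),
                                  allow_reflection = FALSE), 1e-8)
  }
})

test_that("default d_c places the nearest recovered point at unit depth", {
  set.seed(18)
  sh <- gen_shape(8)
  cs <- project_pairs(sh, sh$camera)
  rec <- recover_shape(cs, sh$camera)
  expect_equal(max(rbind(rec$P, rec$Q)[, 3]), -1, tolerance = 1e-8)
})

test_that("inconsistent pairings are refused with a quality warning", {
  set.seed(19)
  sh <- gen_shape(8)
  cs <- project_pairs(sh, sh$camera)
  # destroy the correspondence structure by shuffling q
  bad <- correspondences(cs$p, cs$q[sample(nrow(cs$q)), ])
  expect_warning(expect_error(recover_shape(bad, sh$camera), "refused"),
                 "correspondence quality")
  # force pushes through
  rec <- suppressWarnings(recover_shape(bad, sh$camera, force = TRUE))
  expect_s3_class(rec, "recovered_shape")
})

test_that("parallel-chord images route to the orthographic family handler", {
  # symmetric object seen orthographically: chords parallel in the image
  set.seed(20)
  half <- cbind(runif(8, 0.3, 1), runif(8, -1, 1), runif(8, -3, -1))
  P <- half; Q <- cbind(-half[, 1], half[, 2:3])
  cs <- correspondences(project_orthographic(P)[, 1:2],
                        project_orthographic(Q)[, 1:2])
  rec <- recover_shape(cs, camera(Inf))
  expect_true(rec$orthographic)
  expect_match(rec$free_parameter, "one-parameter")
  # returned member is exactly mirror-symmetric with coplanar midpoints
  expect_lt(max(abs(mirror_reflect(rec$P, rec$plane) - rec$Q)), 1e-9)
  expect_lt(max(abs(plane_distance(rec$M, rec$plane))), 1e-9)
})

test_that("recoveries at growing z_F approach an orthographic family member", {
  set.seed(21)
  half <- cbind(runif(8, 0.3, 1), runif(8, -1, 1), runif(8, -3, -1))
  truth <- list(P = half, Q = cbind(-half[, 1], half[, 2:3]))
  prev <- NULL
  dists <- c()
  for (zf in c(1e2, 1e3, 1e4)) {
    cam <- camera(zf)
    cs <- project_pairs(truth, cam)
    rec <- suppressWarnings(recover_shape(cs, cam, force = TRUE))
    cur <- rbind(rec$P, rec$Q)
    if (!is.null(prev)) dists <- c(dists, procrustes_distance(prev, cur))
    prev <- cur
  }
  # successive recoveries converge onto one member of the orthographic family
  expect_true(all(diff(dists) < 0) || all(dists < 1e-6))
})
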