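test_that("stimulus classes satisfy their symmetry invariants", {
  for (cl in c("A", "B", "D")) {
    s <- generate_stimulus(cl, 101)
    expect_true(s$symmetric)
    expect_lt(asymmetry_penalty(mirrorshape:::stimulus_pair_set(s),
                                restarts = FALSE), 1e-18)
    expect_equal(nrow(s$vertices), 16L)
  }
  for (cl in c("C", "E", "F")) {
    s <- generate_stimulus(cl, 101)
    expect_false(s$symmetric)
    expect_equal(nrow(s$vertices), 16L)
    # no mirror plane anywhere near: grid-search oracle floor is large
    ps <- mirrorshape:::stimulus_pair_set(s)
    expect_gt(oracle_asymmetry_grid(ps$P, ps$Q), 0.05)
  }
  # determinism and seed sensitivity
  expect_identical(generate_stimulus("A", 7)$vertices,
                   generate_stimulus("A", 7)$vertices)
  expect_false(identical(generate_stimulus("A", 7)$vertices,
                         generate_stimulus("A", 8)$vertices))
  expect_error(generate_stimulus("G", 1), "unknown stimulus class")
  # class B shares class A's vertex construction but has no edges
  expect_null(generate_stimulus("B", 5)$edges)
  expect_identical(generate_stimulus("B", 5)$vertices,
                   generate_stimulus("A", 5)$vertices)
  # class C connects all 16 vertices in one path
  sc <- generate_stimulus("C", 5)
  expect_equal(nrow(sc$edges), 15L)
  expect_setequal(as.integer(unique(c(sc$edges))), 1:16)
})

test_that("stimulus generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_stimulus("A", 1))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("model observer is correct on noiseless class-A trials", {
  set.seed(61)
  s1 <- generate_stimulus("A", 1)
  s2 <- generate_stimulus("A", 2)
  same <- run_trial(s1, s1, sigma = 0)
  expect_equal(same$response, "same")
  expect_true(all(same$recovered))
  expect_lt(same$dissimilarity, 1e-6)
  diff <- run_trial(s1, s2, sigma = 0)
  expect_equal(diff$response, "different")
})

test_that("shape constancy is similarity invariance across views (sigma 0)", {
  set.seed(62)
  obs <- model_observer()
  for (i in 1:10) {
    s <- generate_stimulus("A", i)
    tr <- run_trial(s, s, obs, sigma = 0)
    expect_true(all(tr$recovered))
    expect_lt(tr$dissimilarity, 1e-6)
  }
})

test_that("polygonal-line stimuli put the observer at chance", {
  set.seed(63)
  n <- 200L
  responses <- replicate(n, {
    s <- generate_stimulus("C", sample.int(1e6, 1))
    run_trial(s, s, sigma = 0.005)$response
  })
  p_same <- mean(responses == "same")
  # binomial 99% interval around 1/2 at n = 200
  expect_gt(p_same, 0.5 - 2.58 * sqrt(0.25 / n))
  expect_lt(p_same, 0.5 + 2.58 * sqrt(0.25 / n))
})

test_that("d-prime follows the inverse-normal difference with correction", {
  expect_equal(dprime(10, 10, 20, 20)$dprime, 0)
  # H = 0.84, FA = 0.16: d' = qnorm(.84) - qnorm(.16) ~ 1.9889 (frozen from
  # the inverse normal CDF)
  expect_equal(dprime(84, 16, 100, 100)$dprime, 1.988916, tolerance = 1e-4)
  # perfect hits stay finite via the 1/(2n) correction and exceed H = 0.95
  d_perfect <- dprime(20, 4, 20, 20)$dprime
  d_095 <- dprime(19, 4, 20, 20)$dprime
  expect_true(is.finite(d_perfect))
  expect_gt(d_perfect, d_095)
  expect_error(dprime(1, 1, 0, 10), "positive")
  expect_error(dprime(30, 1, 20, 20), "out of range")
  # list interface
  expect_equal(dprime(list(hits = 84, false_alarms = 16, n_signal = 100,
                           n_noise = 100))$dprime, 1.988916,
               tolerance = 1e-4)
})

test_that("experiment reproduces the symmetric-vs-polygonal contrast", {
  res <- run_experiment(classes = c("A", "C"), n_trials = 60, sigma = 0.005,
                        seed = 5)
  dA <- res[res$class == "A", ]
  dC <- res[res$class == "C", ]
  expect_gt(dA$ci_lower, 0)            # reliably above chance
  expect_lt(abs(dC$dprime), dC$ci_upper - dC$dprime)  # CI covers 0
  expect_gt(dA$dprime, dC$dprime + 1)
})

test_that("experiment runs are reproducible and ordering holds across classes", {
  res1 <- run_experiment(classes = c("A", "D", "C", "F"), n_trials = 30,
                         sigma = 0.005, seed = 9)
  res2 <- run_experiment(classes = c("A", "D", "C", "F"), n_trials = 30,
                         sigma = 0.005, seed = 9)
  expect_identical(res1, res2)
  sym <- mean(res1$dprime[res1$class %in% c("A", "D")])
  asym <- mean(res1$dprime[res1$class %in% c("C", "F")])
  expect_gt(sym, asym)
})

test_that("binocular surrogate (reduced noise) does not hurt performance", {
  mono <- run_experiment(classes = "A", n_trials = 40, sigma = 0.01,
                         viewing = "monocular", seed = 13)
  bino <- run_experiment(classes = "A", n_trials = 40, sigma = 0.01,
                         viewing = "binocular", seed = 13)
  expect_gte(bino$dprime, mono$dprime - 0.5)
})

test_that("doubling trials narrows the d-prime standard error by ~sqrt(2)", {
  # binomial sampling-theory oracle at fixed rates
  s1 <- dprime(80, 20, 100, 100)$se
  s2 <- dprime(160, 40, 200, 200)$se
  expect_equal(s1 / s2, sqrt(2), tolerance = 1e-9)
})

test_that("visual angle follows tan(alpha) = S / D", {
  expect_equal(visual_angle(1, 1, degrees = TRUE), 45)
  expect_equal(visual_angle(0, 10), 0)
  expect_equal(visual_angle(1, sqrt(3), degrees = TRUE), 30)
  expect_error(visual_angle(1, 0), "positive")
  expect_error(visual_angle(-1, 1), "non-negative")
})

test_that("procrustes distance is a similarity invariant", {
  set.seed(64)
  X <- matrix(rnorm(48), 16, 3)
  tr <- similarity_transform(random_rotation(), rnorm(3), scale = 1.7)
  expect_lt(procrustes_distance(X, apply_transform(X, tr)), 1e-12)
  Y <- matrix(rnorm(48), 16, 3)
  expect_gt(procrustes_distance(X, Y), 0.1)
  # reflection handling
  Xr <- mirror_reflect(X, plane3d(1, 0, 0, 0))
  expect_lt(procrustes_distance(X, Xr, allow_reflection = TRUE), 1e-12)
  expect_gt(procrustes_distance(X, Xr, allow_reflection = FALSE), 0.01)
})

test_that("procrustes distance agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(65)
  X <- matrix(rnorm(48), 16, 3)
  Y <- X + matrix(rnorm(48, sd = 0.1), 16, 3)
  ours <- procrustes_distance(X, Y, allow_reflection = FALSE)
  # vegan: symmetric Procrustes residual sum of squares on unit-norm data
  ref <- sqrt(vegan::procrustes(X, Y, symmetric = TRUE)$ss)
  expect_equal(ours, ref, tolerance = 1e-6)
})
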