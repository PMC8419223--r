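# Model-observer shape-constancy experiment: six 16-vertex stimulus classes,
# two views 90 degrees apart, a same/different task, and d-prime analysis.
#
# The model observer instantiates the claim that 3D shape constancy rests on
# recovering a mirror-symmetric 3D interpretation from each single view: it
# applies the closed-form symmetry recovery to each (noisy) projected view
# using the stimulus' pair structure, falls back to a depth-free flat
# interpretation when the image is inconsistent with a single mirror
# symmetry, and responds "same" when the two recoveries agree up to a
# similarity transform.  It is one concrete decision model, not a claim
# about the human observer's actual rule.

STIMULUS_CLASSES <- c("A", "B", "C", "D", "E", "F")

with_seed <- function(seed, code) {
  force(seed)  # evaluate before saving RNG state (seed may itself use RNG)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# 8 mirror pairs about the plane x = 0, centered, unit-ish scale
base_symmetric_vertices <- function(n_pairs = 8L) {
  x <- stats::runif(n_pairs, 0.25, 1)
  y <- stats::runif(n_pairs, -1, 1)
  z <- stats::runif(n_pairs, -1, 1)
  P <- cbind(x, y, z)
  Q <- cbind(-x, y, z)
  rbind(P, Q)
}

#' Generate a 16-vertex experiment stimulus
#'
#' Six stimulus classes sharing the same vertex-generation method:
#' \describe{
#'   \item{A}{mirror-symmetric polyhedron with planar lateral faces (8 mirror
#'     pairs about a plane, consecutive pairs joined into quadrilateral
#'     faces, which are automatically planar for mirror pairs);}
#'   \item{B}{the 16 vertices of a class-A object with all edges removed;}
#'   \item{C}{polygonal line: the 16 vertices of a class-A-style object
#'     connected in seeded random order (no mirror plane relates the implied
#'     pairing);}
#'   \item{D}{mirror-symmetric but partially non-planar: class-A vertices
#'     with lateral faces triangulated irregularly so the faces are not
#'     planar polygons (the mirror plane is exact);}
#'   \item{E}{planar asymmetric: one half of a double-size (16-pair)
#'     symmetric object, giving 16 vertices with no mirror plane;}
#'   \item{F}{non-planar asymmetric: class E with an additional random
#'     jitter.}
#' }
#' The `pairs` component gives the point pairing the model observer treats
#' as candidate symmetry correspondences (for C, E, F it pairs points that
#' are not mirror images, so the asymmetry penalty is bounded away from 0).
#'
#' @param class One of `"A" ... "F"`.
#' @param seed Integer seed; identical `(class, seed)` give identical
#'   stimuli.
#' @return Object of class `"stimulus"`: `vertices` (16 x 3, centered),
#'   `pairs` (8 x 2 index matrix), `edges` (2-column index matrix or NULL),
#'   `class`, `seed`, `symmetric` flag.
#' @export
generate_stimulus <- function(class, seed) {
  if (!is.character(class) || length(class) != 1L ||
      !class %in% STIMULUS_CLASSES) {
    stop("unknown stimulus class: must be one of A..F")
  }
  out <- with_seed(seed, {
    switch(class,
      A = {
        V <- base_symmetric_vertices(8L)
        edges <- rbind(cbind(1:8, 9:16),              # mirror rungs
                       cbind(1:8, c(2:8, 1)),         # side loops
                       cbind(9:16, c(10:16, 9)))
        list(vertices = V, pairs = cbind(1:8, 9:16), edges = edges,
             symmetric = TRUE, planar_faces = TRUE)
      },
      B = {
        V <- base_symmetric_vertices(8L)
        list(vertices = V, pairs = cbind(1:8, 9:16), edges = NULL,
             symmetric = TRUE, planar_faces = NA)
      },
      C = {
        V <- base_symmetric_vertices(8L)
        path <- sample(16L)
        edges <- cbind(path[-16L], path[-1L])
        list(vertices = V, pairs = cbind(path[1:8], path[9:16]),
             edges = edges, symmetric = FALSE, planar_faces = NA)
      },
      D = {
        V <- base_symmetric_vertices(8L)
        # irregular triangulation of the side loops -> non-planar surfaces;
        # the vertex set keeps its exact mirror plane
        edges <- rbind(cbind(1:8, 9:16),
                       cbind(1:8, c(2:8, 1)),
                       cbind(9:16, c(10:16, 9)),
                       cbind(1:7, c(10:16)))
        list(vertices = V, pairs = cbind(1:8, 9:16), edges = edges,
             symmetric = TRUE, planar_faces = FALSE)
      },
      E = {
        V <- base_symmetric_vertices(16L)[1:16, , drop = FALSE]  # one half
        edges <- rbind(cbind(1:8, 9:16),
                       cbind(1:8, c(2:8, 1)),
                       cbind(9:16, c(10:16, 9)))
        list(vertices = V, pairs = cbind(1:8, 9:16), edges = edges,
             symmetric = FALSE, planar_faces = TRUE)
      },
      F = {
        V <- base_symmetric_vertices(16L)[1:16, , drop = FALSE]
        V <- V + matrix(stats::runif(48, -0.15, 0.15), 16L, 3L)
        edges <- rbind(cbind(1:8, 9:16),
                       cbind(1:8, c(2:8, 1)),
                       cbind(9:16, c(10:16, 9)))
        list(vertices = V, pairs = cbind(1:8, 9:16), edges = edges,
             symmetric = FALSE, planar_faces = FALSE)
      }
    )
  })
  V <- sweep(out$vertices, 2L, colMeans(out$vertices))  # center at origin
  structure(list(vertices = as_points3d(V), pairs = out$pairs,
                 edges = out$edges, class = class, seed = seed,
                 symmetric = out$symmetric,
                 planar_faces = out$planar_faces),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus class %s (seed %d): %d vertices, %s, %s\n",
              x$class, x$seed, nrow(x$vertices),
              if (x$symmetric) "mirror-symmetric" else "asymmetric",
              if (is.null(x$edges)) "no edges"
              else paste(nrow(x$edges), "edges")))
  invisible(x)
}

stimulus_pair_set <- function(stim) {
  list(P = stim$vertices[stim$pairs[, 1L], , drop = FALSE],
       Q = stim$vertices[stim$pairs[, 2L], , drop = FALSE])
}

#' Similarity-invariant shape dissimilarity (Procrustes residual)
#'
#' Aligns two labeled point sets by translation, uniform scaling and
#' rotation (optionally also reflection) and returns the root-mean-square
#' residual after both sets are centered and scaled to unit norm; 0 iff the
#' sets are identical up to a similarity transform.
#'
#' @param X,Y Point matrices with matching rows.
#' @param allow_reflection Also allow an orthogonal transform with
#'   determinant -1 (default TRUE: recovery from a single view has a mirror
#'   ambiguity).
#' @return Scalar dissimilarity in `[0, sqrt(2)]`.
#' @export
procrustes_distance <- function(X, Y, allow_reflection = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == ncol(Y))
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  nx <- sqrt(sum(X^2)); ny <- sqrt(sum(Y^2))
  if (nx == 0 || ny == 0) return(if (nx == ny) 0 else sqrt(2))
  X <- X / nx; Y <- Y / ny
  sv <- svd(crossprod(Y, X))
  d <- sv$d
  if (!allow_reflection) {
    s <- sign(det(sv$u %*% t(sv$v)))
    if (s < 0) d[length(d)] <- -d[length(d)]
  }
  # optimal scaling of X onto Y: residual^2 = 1 - (sum d)^2 (both unit norm)
  sqrt(max(0, 1 - sum(d)^2))
}

#' Model observer configuration
#'
#' @param z_F Camera focal distance (image plane to projection center).
#' @param viewing_distance Distance of the stimulus centroid from the image
#'   plane (stimulus placed at `z = -viewing_distance`).
#' @param threshold Decision criterion on the similarity-invariant
#'   dissimilarity between the two recovered shapes; respond "same" below it.
#'   The default sits between the recovery noise of repeated views of one
#'   object and the typical shape distance between two independently drawn
#'   objects (pilot calibration; see the package vignette).
#' @param max_angular_residual Refusal criterion for the symmetry
#'   interpretation: recovery is attempted only when the RMS angular
#'   misalignment (radians) between the pair chords and the directions to
#'   the fitted vanishing point is below this value.  The measure is
#'   scale-free, so it works whether the vanishing point falls near or far
#'   from the image.
#' @return Object of class `"model_observer"`.
#' @export
model_observer <- function(z_F = 2, viewing_distance = 4, threshold = 0.35,
                           max_angular_residual = 0.2) {
  structure(list(z_F = z_F, viewing_distance = viewing_distance,
                 threshold = threshold,
                 max_angular_residual = max_angular_residual),
            class = "model_observer")
}

place_stimulus <- function(stim, rotation, viewing_distance) {
  V <- stim$vertices %*% t(rotation)
  V <- sweep(V, 2L, c(0, 0, -viewing_distance), "+")
  list(P = V[stim$pairs[, 1L], , drop = FALSE],
       Q = V[stim$pairs[, 2L], , drop = FALSE])
}

observe_view <- function(stim, rotation, observer, sigma) {
  cam <- camera(observer$z_F)
  placed <- place_stimulus(stim, rotation, observer$viewing_distance)
  cs <- project_pairs(placed, cam, sigma = sigma)
  vp <- tryCatch(estimate_vanishing_point(cs), error = function(e) NULL)
  rec <- NULL
  if (!is.null(vp) && !vp$orthographic &&
      vp$angular_residual <= observer$max_angular_residual) {
    rec <- tryCatch(
      suppressWarnings(recover_shape(cs, cam, force = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(rec)) {
    list(points = NULL, recovered = FALSE)
  } else {
    list(points = rbind(rec$P, rec$Q), recovered = TRUE)
  }
}

#' Run one same/different trial of the shape-constancy task
#'
#' Shows `stimulusA` from a random view and `stimulusB` from a view rotated
#' by `view_separation` (default 90 degrees) about a random axis through the
#' centroid, perturbs both images with Gaussian coordinate noise, lets the
#' model observer recover a 3D interpretation of each view, and responds
#' "same" if the recoveries agree up to a similarity transform.  When the
#' symmetry interpretation is refused for either view (no consistent
#' vanishing point: asymmetric or degenerate stimuli), the observer has no
#' 3D shape to compare and guesses, so its responses sit at chance over
#' trials.  Pass the same stimulus twice for a "same" trial.  Uses the
#' current RNG state.
#'
#' @param stimulusA,stimulusB [generate_stimulus()] objects of equal class.
#' @param observer A [model_observer()].
#' @param view_separation Angle between the two viewing directions (radians).
#' @param sigma Image noise standard deviation (image units).
#' @return List with `response` (`"same"`/`"different"`), `dissimilarity`,
#'   and the two views' `recovered` flags.
#' @export
run_trial <- function(stimulusA, stimulusB, observer = model_observer(),
                      view_separation = pi / 2, sigma = 0.005) {
  stopifnot(inherits(stimulusA, "stimulus"), inherits(stimulusB, "stimulus"),
            inherits(observer, "model_observer"))
  for (attempt in 1:5) {
    R1 <- random_rotation()
    axis <- stats::rnorm(3)
    R2 <- rotation_matrix(view_separation, axis) %*% R1
    v1 <- tryCatch(observe_view(stimulusA, R1, observer, sigma),
                   error = function(e) NULL)
    v2 <- tryCatch(observe_view(stimulusB, R2, observer, sigma),
                   error = function(e) NULL)
    if (!is.null(v1) && !is.null(v2)) {
      if (!v1$recovered || !v2$recovered) {
        return(list(response = sample(c("same", "different"), 1L),
                    dissimilarity = NA_real_,
                    recovered = c(v1$recovered, v2$recovered)))
      }
      d <- procrustes_distance(v1$points, v2$points)
      return(list(response = if (d < observer$threshold) "same" else
                    "different",
                  dissimilarity = d,
                  recovered = c(v1$recovered, v2$recovered)))
    }
    # degenerate projection for the sampled view: resample
  }
  stop("could not sample a non-degenerate pair of views")
}

#' Signal-detection discriminability d'
#'
#' `d' = qnorm(H) - qnorm(FA)` from hit and false-alarm counts, with the
#' standard rate correction replacing 0 and 1 by `1/(2n)` and `1 - 1/(2n)`
#' so the estimate stays finite.  Chance performance gives `d' = 0`.
#'
#' @param hits Number of hits (or a list with fields `hits`, `false_alarms`,
#'   `n_signal`, `n_noise`).
#' @param false_alarms Number of false alarms.
#' @param n_signal,n_noise Numbers of signal and noise trials (`> 0`).
#' @return List with `dprime`, corrected rates `H`, `FA`, and the standard
#'   error `se` of `dprime` (delta method on the binomial rates).
#' @export
dprime <- function(hits, false_alarms = NULL, n_signal = NULL,
                   n_noise = NULL) {
  if (is.list(hits)) {
    counts <- hits
    hits <- counts$hits; false_alarms <- counts$false_alarms
    n_signal <- counts$n_signal; n_noise <- counts$n_noise
  }
  if (is.null(n_signal) || is.null(n_noise) || n_signal <= 0 || n_noise <= 0) {
    stop("n_signal and n_noise must be positive")
  }
  if (hits < 0 || false_alarms < 0 || hits > n_signal ||
      false_alarms > n_noise) {
    stop("counts out of range")
  }
  clamp <- function(k, n) min(max(k / n, 1 / (2 * n)), 1 - 1 / (2 * n))
  H <- clamp(hits, n_signal)
  FA <- clamp(false_alarms, n_noise)
  dp <- stats::qnorm(H) - stats::qnorm(FA)
  se <- sqrt(H * (1 - H) / (n_signal * stats::dnorm(stats::qnorm(H))^2) +
             FA * (1 - FA) / (n_noise * stats::dnorm(stats::qnorm(FA))^2))
  list(dprime = dp, H = H, FA = FA, se = se)
}

#' Run the shape-constancy experiment
#'
#' For each stimulus class, runs `n_trials` "same" trials (one object, two
#' views 90 degrees apart) and `n_trials` "different" trials (two objects of
#' the same class from different seeds) and summarizes performance as d'
#' ("different" is the signal: a hit is responding "different" on a
#' different-objects trial).  The binocular viewing condition is simulated
#' as reduced image noise (`sigma / 3`), a stand-in for the extra
#' reliability disparity would provide; no disparity computation is
#' performed.
#'
#' @param classes Stimulus classes to test.
#' @param n_trials Trials per trial type (so `2 * n_trials` per class).
#' @param sigma Monocular image noise standard deviation.
#' @param viewing `"monocular"` or `"binocular"` (noise `sigma/3`).
#' @param observer A [model_observer()].
#' @param view_separation Angle between views (radians).
#' @param seed Integer seed making the whole run reproducible.
#' @return `data.frame` with one row per class: counts, corrected rates,
#'   `dprime`, standard error and 95% CI bounds.
#' @export
run_experiment <- function(classes = STIMULUS_CLASSES, n_trials = 50L,
                           sigma = 0.005,
                           viewing = c("monocular", "binocular"),
                           observer = model_observer(),
                           view_separation = pi / 2, seed = 1L) {
  viewing <- match.arg(viewing)
  sigma_eff <- if (viewing == "binocular") sigma / 3 else sigma
  with_seed(seed, {
    rows <- lapply(classes, function(cl) {
      n_hit <- 0L; n_fa <- 0L
      for (i in seq_len(n_trials)) {
        s_seed <- sample.int(.Machine$integer.max, 2L)
        stimA <- generate_stimulus(cl, s_seed[1L])
        stimB <- generate_stimulus(cl, s_seed[2L])
        same_tr <- run_trial(stimA, stimA, observer, view_separation,
                             sigma_eff)
        diff_tr <- run_trial(stimA, stimB, observer, view_separation,
                             sigma_eff)
        if (diff_tr$response == "different") n_hit <- n_hit + 1L
        if (same_tr$response == "different") n_fa <- n_fa + 1L
      }
      sdt <- dprime(n_hit, n_fa, n_trials, n_trials)
      data.frame(class = cl, viewing = viewing, n_trials = n_trials,
                 hits = n_hit, false_alarms = n_fa,
                 hit_rate = sdt$H, fa_rate = sdt$FA,
                 dprime = sdt$dprime, se = sdt$se,
                 ci_lower = sdt$dprime - 1.96 * sdt$se,
                 ci_upper = sdt$dprime + 1.96 * sdt$se)
    })
    do.call(rbind, rows)
  })
}

#' Visual angle subtended by a linear extent
#'
#' `alpha = atan(S / D)`: the classical size-constancy relation between an
#' object's linear extent `S` orthogonal to the line of sight, its viewing
#' distance `D`, and its angular size.
#'
#' @param S Linear extent (`>= 0`).
#' @param D Viewing distance (`> 0`).
#' @param degrees Return degrees instead of radians.
#' @return Visual angle.
#' @export
visual_angle <- function(S, D, degrees = FALSE) {
  if (any(D <= 0)) stop("viewing distance must be positive")
  if (any(S < 0)) stop("linear extent must be non-negative")
  a <- atan(S / D)
  if (degrees) a * 180 / pi else a
}
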