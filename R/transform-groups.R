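# Sample-based verification of transformation-group axioms and invariants.
# Groups may be infinite; these checks can only falsify on the sampled
# elements, and every report says so.

#' A finite sample of transformations with a composition rule
#'
#' Represents a (possibly infinite) set of transformations by a finite sample
#' of elements, a composition rule, and an action on instances.  Element
#' equality is judged by comparing actions on a probe set, so elements can be
#' arbitrary R objects (numbers, matrices, functions).
#'
#' @param elements List (or vector) of sampled transformations.
#' @param compose Function `(a, b) -> element` giving the composition `a` after
#'   `b`.  It may signal an error for incompatible elements; such failures are
#'   reported as closure failures, not crashes.
#' @param apply Function `(element, instance) -> instance` giving the action of
#'   an element on an instance (a point set, a number, ...).
#' @param probes List of instances used to compare elements by their action.
#' @param member Optional predicate `(element) -> logical`: whether an element
#'   (e.g. a composition) belongs to the mathematical set even if outside the
#'   sample; used to exclude out-of-window compositions from the closure check
#'   for windowed samples of infinite groups.  `NULL` means membership is
#'   judged against the sampled elements only.
#' @return Object of class `"transformation_set"`.
#' @examples
#' translations(-2:2)
#' @export
transformation_set <- function(elements, compose, apply, probes,
                               member = NULL) {
  stopifnot(is.function(compose), is.function(apply), length(probes) >= 1L)
  elements <- as.list(elements)
  if (length(elements) < 1L) stop("need at least one element")
  structure(list(elements = elements, compose = compose, apply = apply,
                 probes = probes, member = member),
            class = "transformation_set")
}

#' One-dimensional translations as a transformation set
#'
#' Translations of the real line under addition, sampled on a finite window of
#' offsets.  Compositions falling outside the window are excluded from the
#' closure check via the `member` predicate (the mathematical group is
#' infinite; the sample is a compact window).
#'
#' @param offsets Numeric vector of sampled translation offsets.
#' @param window Closed interval of offsets regarded as in-sample for closure.
#' @return A [transformation_set()].
#' @export
translations <- function(offsets, window = range(offsets)) {
  transformation_set(
    elements = as.list(offsets),
    compose = function(a, b) a + b,
    apply = function(el, x) x + el,
    probes = list(0, 1, -2.5),
    member = function(el) el >= window[1] && el <= window[2]
  )
}

#' Planar rotations by multiples of an angle as a transformation set
#'
#' @param k Number of elements (rotations by `2*pi*j/k`, `j = 0..k-1`).
#' @param axis Rotation axis (see [rotation_matrix()]).
#' @return A [transformation_set()] of 3x3 rotation matrices.
#' @export
cyclic_rotations <- function(k = 4L, axis = "z") {
  angles <- 2 * pi * (seq_len(k) - 1L) / k
  transformation_set(
    elements = lapply(angles, rotation_matrix, axis = axis),
    compose = function(a, b) a %*% b,
    apply = function(el, x) as_points3d(x) %*% t(el),
    probes = list(rbind(c(1, 0, 0), c(0.3, -2, 1)))
  )
}

#' The set of perspective projections (not a group)
#'
#' 3D-to-2D perspective projections sampled over several focal distances.
#' Composition is undefined (the codomain is the image plane, not 3D space)
#' and no element inverts another, so the axiom report flags closure and
#' inverse failures.
#'
#' @param z_F_values Focal distances to sample.
#' @return A [transformation_set()].
#' @export
perspective_projection_set <- function(z_F_values = c(1, 2, 5)) {
  transformation_set(
    elements = lapply(z_F_values, camera),
    compose = function(a, b) {
      stop("composition of two 3D->2D projections is undefined")
    },
    apply = function(el, x) project_perspective(x, el),
    probes = list(rbind(c(0.1, 0.2, -1), c(-0.4, 0.5, -2)))
  )
}

act_on_probes <- function(set, el) {
  lapply(set$probes, function(p) set$apply(el, p))
}

probe_difference <- function(a, b) {
  max(mapply(function(x, y) {
    x <- as.numeric(unlist(x)); y <- as.numeric(unlist(y))
    if (length(x) != length(y)) return(Inf)
    max(abs(x - y))
  }, a, b))
}

#' Check group axioms on a sampled transformation set
#'
#' Numerically checks closure, identity, inverse and associativity on the
#' sampled elements.  Element equality means equal action on the probe
#' instances within `tol`.  This is a sampled check: it can falsify the axioms
#' but cannot prove them for an infinite set, and the returned report records
#' the sample size.
#'
#' @param set A [transformation_set()] with at least 2 elements.
#' @param tol Numeric tolerance on probe actions.
#' @param max_pairs Cap on the number of element pairs/triples sampled.
#' @return A list of class `"group_axiom_report"` with logical fields
#'   `closure`, `identity`, `inverse`, `associativity`, worst-case deviations,
#'   and the sample description.
#' @export
check_group_axioms <- function(set, tol = 1e-9, max_pairs = 400L) {
  stopifnot(inherits(set, "transformation_set"))
  els <- set$elements
  n <- length(els)
  if (n < 2L) stop("need at least 2 sampled elements")
  probe_imgs <- lapply(els, function(e) act_on_probes(set, e))

  find_element <- function(action) {
    devs <- vapply(probe_imgs, function(pi) probe_difference(pi, action),
                   numeric(1))
    j <- which.min(devs)
    list(index = j, dev = devs[j])
  }

  # identity: element acting as the identity on all probes
  id_action <- set$probes
  id_found <- find_element(id_action)
  identity_ok <- id_found$dev <= tol

  # closure: compositions of sampled pairs act like some sampled element
  # (or are accepted by the membership predicate)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  if (nrow(idx) > max_pairs) idx <- idx[seq_len(max_pairs), , drop = FALSE]
  closure_dev <- 0
  closure_ok <- TRUE
  n_excluded <- 0L
  for (r in seq_len(nrow(idx))) {
    comp <- tryCatch(set$compose(els[[idx$i[r]]], els[[idx$j[r]]]),
                     error = function(e) e)
    if (inherits(comp, "error")) { closure_ok <- FALSE; closure_dev <- Inf; next }
    if (!is.null(set$member)) {
      inset <- tryCatch(isTRUE(set$member(comp)), error = function(e) FALSE)
      if (!inset) { n_excluded <- n_excluded + 1L; next }
    }
    action <- tryCatch(act_on_probes(set, comp), error = function(e) e)
    if (inherits(action, "error")) { closure_ok <- FALSE; closure_dev <- Inf; next }
    best <- find_element(action)
    closure_dev <- max(closure_dev, best$dev)
    if (best$dev > tol) closure_ok <- FALSE
  }

  # inverses: for each element, some sampled element composes to the identity
  inverse_dev <- 0
  inverse_ok <- TRUE
  for (i in seq_len(n)) {
    devs <- vapply(seq_len(n), function(j) {
      comp <- tryCatch(set$compose(els[[i]], els[[j]]), error = function(e) e)
      if (inherits(comp, "error")) return(Inf)
      action <- tryCatch(act_on_probes(set, comp), error = function(e) e)
      if (inherits(action, "error")) return(Inf)
      probe_difference(action, id_action)
    }, numeric(1))
    d <- min(devs)
    inverse_dev <- max(inverse_dev, d)
    if (d > tol) inverse_ok <- FALSE
  }

  # associativity on sampled triples
  assoc_dev <- 0
  assoc_ok <- TRUE
  n_tri <- min(n, 5L)
  for (i in seq_len(n_tri)) for (j in seq_len(n_tri)) for (k in seq_len(n_tri)) {
    lhs <- tryCatch(set$compose(els[[i]], set$compose(els[[j]], els[[k]])),
                    error = function(e) e)
    rhs <- tryCatch(set$compose(set$compose(els[[i]], els[[j]]), els[[k]]),
                    error = function(e) e)
    if (inherits(lhs, "error") || inherits(rhs, "error")) {
      assoc_ok <- FALSE; assoc_dev <- Inf; next
    }
    d <- probe_difference(act_on_probes(set, lhs), act_on_probes(set, rhs))
    assoc_dev <- max(assoc_dev, d)
    if (d > tol) assoc_ok <- FALSE
  }

  structure(list(
    closure = closure_ok, identity = identity_ok, inverse = inverse_ok,
    associativity = assoc_ok,
    deviations = c(closure = closure_dev, identity = id_found$dev,
                   inverse = inverse_dev, associativity = assoc_dev),
    identity_index = if (identity_ok) id_found$index else NA_integer_,
    n_elements = n, n_pairs_checked = nrow(idx),
    n_compositions_excluded = n_excluded, tol = tol,
    note = paste("Sampled check on", n, "elements; axioms are universally",
                 "quantified and can only be falsified, not proven, by this",
                 "report.")
  ), class = "group_axiom_report")
}

#' @export
print.group_axiom_report <- function(x, ...) {
  cat("Group axiom report (sampled,", x$n_elements, "elements):\n")
  for (ax in c("closure", "identity", "inverse", "associativity")) {
    cat(sprintf("  %-14s %s  (worst deviation %.3g)\n", ax,
                if (isTRUE(x[[ax]])) "PASS" else "FAIL", x$deviations[[ax]]))
  }
  if (x$n_compositions_excluded > 0L) {
    cat("  ", x$n_compositions_excluded,
        "out-of-window compositions excluded from closure\n")
  }
  invisible(x)
}

#' Maximum deviation of a candidate invariant under a transformation set
#'
#' Evaluates `max |feature(T(x)) - feature(x)|` over all sampled elements `T`
#' and instances `x`.  A deviation of 0 (within tolerance) certifies sampled
#' invariance of the feature.
#'
#' @param set A [transformation_set()].
#' @param feature Function `instance -> number`.
#' @param instances Non-empty list of instances.
#' @return Maximum absolute deviation (single number).
#' @export
invariant_deviation <- function(set, feature, instances) {
  stopifnot(inherits(set, "transformation_set"), is.function(feature))
  if (length(instances) == 0L) stop("need at least one instance")
  max(vapply(set$elements, function(el) {
    max(vapply(instances, function(x) {
      abs(feature(set$apply(el, x)) - feature(x))
    }, numeric(1)))
  }, numeric(1)))
}

#' A deterministic natural-law system (state evolution map)
#'
#' Wraps an `evolve: state -> state` map over a fixed duration, used in
#' commutation diagrams testing whether a transformation is a symmetry of the
#' law.
#'
#' @param evolve Function `state -> state` (deterministic).
#' @return Object of class `"natural_law_system"`.
#' @export
natural_law_system <- function(evolve) {
  stopifnot(is.function(evolve))
  structure(list(evolve = evolve), class = "natural_law_system")
}

#' Commutator of a natural law with a transformation
#'
#' Measures `||N(Theta(u)) - Theta(N(u))||` (Euclidean norm on flattened
#' states): zero certifies, for state `u`, that `Theta` is a symmetry of the
#' evolution law `N`, i.e. that evolving a transformed experiment equals
#' transforming the evolved one.
#'
#' @param system A [natural_law_system()].
#' @param theta Function `state -> state` (the transformation).
#' @param state Initial state `u`.
#' @return Scalar deviation.
#' @export
law_transform_commutator <- function(system, theta, state) {
  stopifnot(inherits(system, "natural_law_system"), is.function(theta))
  a <- unlist(system$evolve(theta(state)))
  b <- unlist(theta(system$evolve(state)))
  if (length(a) != length(b)) stop("state dimension mismatch")
  sqrt(sum((a - b)^2))
}

#' Constant-force motion as a natural-law system
#'
#' A particle of mass `m` at rest accelerated by a constant force `F` along x
#' for duration `t`: the state `(x, y)` evolves to `(x + F t^2 / (2 m), y)`.
#'
#' @param force Force along x.
#' @param mass Particle mass.
#' @param duration Evolution duration.
#' @return A [natural_law_system()] on states `c(x, y)`.
#' @export
constant_force_system <- function(force, mass, duration) {
  d <- (force / mass) * duration^2 / 2
  natural_law_system(function(state) state + c(d, 0))
}

#' Inverse-square scaling of gravitational fall (Moon/Earth worked example)
#'
#' Computes how far a circularly orbiting body falls toward the center in one
#' second, `fall_at_orbit = (1/2) (2 pi / period)^2 radius * (1 s)^2`, and the
#' fall predicted at a point `distance_ratio` times closer under the
#' inverse-square law, `fall_scaled = fall_at_orbit * distance_ratio^2`.
#' With the Moon's sidereal period and orbital radius and ratio 60 this
#' reproduces Newton's classical consistency check against Galilean free fall
#' at the Earth's surface (about 4.9 m in the first second).
#'
#' @param period Orbital period in seconds (use [days()] for day inputs).
#' @param radius Orbital radius in meters.
#' @param distance_ratio Ratio of orbital distance to the closer distance.
#' @return List with `fall_at_orbit` and `fall_scaled`, meters fallen in 1 s.
#' @examples
#' inverse_square_fall(days(27.3), 3.84e8, 60)
#' @export
inverse_square_fall <- function(period, radius, distance_ratio) {
  if (any(c(period, radius, distance_ratio) <= 0)) {
    stop("period, radius and distance_ratio must be positive")
  }
  omega <- 2 * pi / period
  fall <- 0.5 * omega^2 * radius  # times (1 s)^2
  list(fall_at_orbit = fall, fall_scaled = fall * distance_ratio^2)
}

#' Convert days to seconds
#'
#' Fixed day length of 86,400 s.
#'
#' @param d Number of days.
#' @return Seconds.
#' @export
days <- function(d) d * 86400
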