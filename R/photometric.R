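# Lightness and color constancy models: multiplicative reflectance, the
# illuminant-invariant lightness ratio, and von Kries diagonal adaptation
# under low-dimensional linear reflectance models.
#
# Spectral convention: wavelengths 400-700 nm sampled every 10 nm
# (31 samples).  Cone fundamentals are synthetic Gaussian sensitivity curves
# (three fixed positive, linearly independent functions); no measured human
# fundamentals are claimed.

#' Spectral wavelength grid (nm)
#'
#' The package's fixed visible-spectrum grid: 400 to 700 nm in 10 nm steps.
#'
#' @return Numeric vector of 31 wavelengths.
#' @export
wavelength_grid <- function() seq(400, 700, by = 10)

#' Surface patch (albedo or reflectance spectrum)
#'
#' @param reflectance Either a single albedo in `[0, 1]` or a reflectance
#'   spectrum on [wavelength_grid()] with all values in `[0, 1]`.
#' @return Object of class `"surface_patch"`.
#' @export
surface_patch <- function(reflectance) {
  reflectance <- as.numeric(reflectance)
  if (!length(reflectance) %in% c(1L, length(wavelength_grid()))) {
    stop("reflectance must be scalar albedo or a spectrum on the 31-sample grid")
  }
  if (any(reflectance < 0 | reflectance > 1)) {
    stop("reflectance values must lie in [0, 1]")
  }
  structure(list(S = reflectance), class = "surface_patch")
}

#' Illuminant (intensity or spectrum)
#'
#' @param power A single non-negative intensity or a non-negative spectral
#'   power distribution on [wavelength_grid()].
#' @return Object of class `"illuminant"`.
#' @export
illuminant <- function(power) {
  power <- as.numeric(power)
  if (!length(power) %in% c(1L, length(wavelength_grid()))) {
    stop("power must be scalar or a spectrum on the 31-sample grid")
  }
  if (any(power < 0)) stop("illuminant power must be non-negative")
  structure(list(L = power), class = "illuminant")
}

#' Blackbody (Planck) illuminant spectrum
#'
#' Relative spectral power of a blackbody radiator at temperature `T_K`
#' (Planck's law on [wavelength_grid()], normalized to unit mean) — the
#' package's daylight-like illuminant family (roughly 4000-10000 K).
#'
#' @param T_K Blackbody temperature in kelvin.
#' @return An [illuminant()].
#' @export
blackbody_illuminant <- function(T_K) {
  stopifnot(T_K > 0)
  lam <- wavelength_grid() * 1e-9
  h <- 6.62607015e-34; c0 <- 299792458; kB <- 1.380649e-23
  B <- (2 * h * c0^2 / lam^5) / (exp(h * c0 / (lam * kB * T_K)) - 1)
  illuminant(B / mean(B))
}

#' Reflected light from a surface patch
#'
#' Pointwise product `L_R = L_I * S` of illuminant power and reflectance
#' (scalars or spectra).
#'
#' @param ill An [illuminant()] (or non-negative numeric).
#' @param patch A [surface_patch()] (or numeric reflectance in `[0, 1]`).
#' @return Reflected intensity (scalar) or spectrum.
#' @export
reflected_light <- function(ill, patch) {
  L <- if (inherits(ill, "illuminant")) ill$L else as.numeric(ill)
  S <- if (inherits(patch, "surface_patch")) patch$S else as.numeric(patch)
  if (any(L < 0)) stop("illuminant power must be non-negative")
  if (any(S < 0 | S > 1)) stop("reflectance must lie in [0, 1]")
  L * S
}

#' Lightness ratio of two patches (illuminant-invariant)
#'
#' `L_R(A) / L_R(B)` under a shared illuminant: equals `S_A / S_B` exactly,
#' independent of the illuminant intensity — the classical ratio invariant of
#' lightness constancy.
#'
#' @param patchA,patchB Surface patches (scalar albedo case).
#' @param ill Shared illuminant intensity.
#' @return Scalar ratio.
#' @export
lightness_ratio <- function(patchA, patchB, ill) {
  a <- reflected_light(ill, patchA)
  b <- reflected_light(ill, patchB)
  if (any(b == 0)) stop("denominator patch reflects no light")
  a / b
}

#' Synthetic cone fundamentals
#'
#' Three fixed positive Gaussian sensitivity curves (peaks 445, 540 and
#' 565 nm), linearly independent on [wavelength_grid()].  Synthetic stand-ins
#' for cone spectral sensitivities; not measured human fundamentals.
#'
#' @return 31 x 3 matrix (columns S, M, L channels).
#' @export
cone_fundamentals <- function() {
  lam <- wavelength_grid()
  g <- function(mu, sd) exp(-0.5 * ((lam - mu) / sd)^2)
  m <- cbind(S = g(445, 25), M = g(540, 35), L = g(565, 40))
  m
}

#' Cone absorptions of a patch under an illuminant
#'
#' `a_k = sum_lambda cone_k(lambda) L(lambda) S(lambda)` over the spectral
#' grid.
#'
#' @param patch A [surface_patch()] with a spectral reflectance.
#' @param ill An [illuminant()] with a spectral power distribution.
#' @param cones Cone sensitivity matrix (default [cone_fundamentals()]).
#' @return Numeric length-3 vector of absorptions.
#' @export
cone_absorptions <- function(patch, ill, cones = cone_fundamentals()) {
  L_R <- reflected_light(ill, patch)
  if (length(L_R) != nrow(cones)) {
    stop("spectral reflectance and illuminant required (31-sample grid)")
  }
  drop(crossprod(cones, L_R))
}

#' Von Kries diagonal adaptation
#'
#' Predicts cone absorptions under a second illuminant by independently
#' scaling each channel: `a2_k = g_k * a1_k`.
#'
#' @param absorptions Length-3 vector (or 3-column matrix, one row per patch)
#'   of cone absorptions under the first illuminant.
#' @param gains Positive length-3 gain vector.
#' @return Scaled absorptions (same shape as input).
#' @export
von_kries_adapt <- function(absorptions, gains) {
  gains <- as.numeric(gains)
  if (length(gains) != 3L || any(!is.finite(gains)) || any(gains <= 0)) {
    stop("gains must be three positive numbers")
  }
  if (is.matrix(absorptions)) {
    sweep(absorptions, 2L, gains, "*")
  } else {
    absorptions * gains
  }
}

#' Fit von Kries gains from patches seen under two illuminants
#'
#' Channel-wise least-squares gains mapping the absorptions of one or more
#' patches under `ill1` to their absorptions under `ill2`; also reports the
#' root-mean-square relative residual of the fitted diagonal map.  The fit is
#' exact (residual ~ 0) iff the patches' reflectances lie in a 3-dimensional
#' linear model adapted to the cones/illuminant pair (see
#' [von_kries_exact_basis()]); non-positive fitted gains are flagged.
#'
#' @param patches List of [surface_patch()] objects (spectral).
#' @param ill1,ill2 Two [illuminant()] objects (spectral).
#' @param cones Cone sensitivity matrix.
#' @return List with `gains`, `residual` (RMS of `a2 - g * a1` relative to
#'   RMS of `a2`), and `degenerate` flag.
#' @export
fit_von_kries_gains <- function(patches, ill1, ill2,
                                cones = cone_fundamentals()) {
  A1 <- t(vapply(patches, cone_absorptions, numeric(3), ill = ill1,
                 cones = cones))
  A2 <- t(vapply(patches, cone_absorptions, numeric(3), ill = ill2,
                 cones = cones))
  gains <- vapply(1:3, function(k) {
    denom <- sum(A1[, k]^2)
    if (denom == 0) return(NA_real_)
    sum(A1[, k] * A2[, k]) / denom
  }, numeric(1))
  degenerate <- any(!is.finite(gains)) || any(gains <= 0)
  if (degenerate) warning("degenerate von Kries fit: non-positive gains")
  pred <- sweep(A1, 2L, gains, "*")
  residual <- sqrt(sum((pred - A2)^2)) / max(sqrt(sum(A2^2)),
                                             .Machine$double.eps)
  list(gains = gains, residual = residual, degenerate = degenerate)
}

#' Reflectance basis exactly diagonalized by von Kries adaptation
#'
#' Constructs a 3-function linear reflectance model for which the change of
#' cone absorptions between two given illuminants is *exactly* a diagonal
#' (von Kries) gain map with the prescribed channel gains.  Channel `j`
#' satisfies `a2_j = g_j a1_j` for every reflectance `S` in the model iff the
#' spectral vector `w_j = cone_j * (L2 - g_j L1)` is orthogonal to the whole
#' reflectance subspace; the basis is therefore built by projecting three
#' smooth positive seed spectra onto the orthogonal complement of
#' `span(w_1, w_2, w_3)`.  Reflectances outside the resulting span are mapped
#' only approximately.  This is the exact-limit construction behind diagonal
#' adaptation under low-dimensional linear reflectance models; generic smooth
#' bases give small but non-zero residuals.
#'
#' @param ill1,ill2 Two spectral [illuminant()] objects.
#' @param gains Three positive target channel gains, or `NULL` (default) to
#'   use the natural gains of a flat gray reference,
#'   `g_j = (cone_j . L2 sbar) / (cone_j . L1 sbar)` — with these the flat
#'   spectrum is already admissible and the basis stays positive.
#' @param cones Cone sensitivity matrix.
#' @return 31 x 3 matrix of basis functions (columns), with the gains as the
#'   `"gains"` attribute.
#' @export
von_kries_exact_basis <- function(ill1, ill2, gains = NULL,
                                  cones = cone_fundamentals()) {
  lam <- wavelength_grid()
  sbar <- rep(0.5, length(lam))
  if (is.null(gains)) {
    gains <- vapply(1:3, function(j) {
      sum(cones[, j] * ill2$L * sbar) / sum(cones[, j] * ill1$L * sbar)
    }, numeric(1))
  }
  stopifnot(length(gains) == 3L, all(gains > 0))
  seeds <- cbind(sbar,
                 0.2 + 0.6 * (lam - 400) / 300,
                 0.2 + 0.6 * exp(-0.5 * ((lam - 550) / 80)^2))
  W <- sapply(1:3, function(j) cones[, j] * (ill2$L - gains[j] * ill1$L))
  proj <- diag(nrow(W)) - W %*% solve(crossprod(W), t(W))
  basis <- proj %*% seeds
  colnames(basis) <- paste0("b", 1:3)
  attr(basis, "gains") <- gains
  basis
}

#' Build surface patches inside a linear reflectance model
#'
#' Combines basis functions with the given coefficients, rescaling the result
#' into `[0.02, 0.98]` *jointly* (one affine map applied to all patches, so
#' patches stay inside the span of the basis plus a constant only if the
#' shift is zero; by default only positive scaling is applied and an error is
#' raised if a shift would be needed).
#'
#' @param basis 31 x k basis matrix.
#' @param coefficients Matrix (patches x k) of coefficients.
#' @return List of [surface_patch()] objects.
#' @export
patches_from_basis <- function(basis, coefficients) {
  coefficients <- as.matrix(coefficients)
  stopifnot(ncol(coefficients) == ncol(basis))
  refl <- basis %*% t(coefficients)       # 31 x n_patches
  lo <- min(refl); hi <- max(refl)
  if (lo < 0) {
    stop("coefficient combination leaves [0, 1]; use non-negative combinations")
  }
  if (hi > 1) refl <- refl * (0.98 / hi)  # pure scaling keeps the span
  apply(refl, 2L, surface_patch, simplify = FALSE)
}
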