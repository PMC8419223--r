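# mirrorshape

Recovering 3D mirror-symmetric shapes from a single 2D perspective image,
and the invariance/constancy toolkit around it.

## The problem

Inferring a 3D scene from one 2D image is an ill-posed inverse problem: the
perspective map 3D→2D is not a group, has no inverse and no invariants.
`mirrorshape` implements the resolution that mirror symmetry provides.  For
an object with a symmetry plane, the chords joining mirror-paired points are
all parallel, so their images meet in a single vanishing point `v`.  In the
canonical frame with `v = (x_v, 0)`, image plane `z = 0` and projection
center `F = (0, 0, z_F)`:

- the symmetry plane is `−(x_v/z_F)·x + z + d_c = 0`, with vanishing line
  `x_h = −z_F²/x_v`;
- the image of the 3D midpoint of a pair lies on its chord at the
  **harmonic mean** of the two polar radii about `v`:
  `h = 2·r_φ·r_ψ/(r_φ + r_ψ)` — computable from image data alone;
- pair depths follow in closed form:
  `z_Φ = z_F + 2·r_ψ·(z_F + d_c)·x_h / ((r_φ + r_ψ)(x_m − x_h))`,
  and symmetrically for `z_Ψ`.

One monocular view fixes shape only up to the one-parameter family indexed
by `d_c` (an overall distance/size — a similarity transform).  For noisy
images the package minimizes the energy functional
`E(X) = ‖A(X) − Y‖ + λ‖P(X)‖` (reprojection error plus weighted asymmetry
penalty), whose minimizer with `λ = σ_data²/σ_prior²` is the MAP estimate
under Gaussian noise and a Gaussian symmetry prior.

Around this core the package provides: numerical verification of
transformation-group axioms and invariants (including the translated
constant-force experiment and the inverse-square lunar-fall example); a
least-action test bench (action quadrature, Euler–Lagrange residuals,
stationarity, and Noether momentum/energy conservation checks); lightness
ratios and von Kries diagonal color adaptation under 3-basis linear
reflectance models; and a model-observer shape-constancy experiment with
six 16-vertex stimulus classes, 90°-apart views, and d′ analysis.

It is intended for computational vision researchers who want a tested,
reproducible reference implementation of symmetry-based monocular shape
recovery and of the model-observer experiment logic built on it.

## Worked example

Recover a random mirror-symmetric 16-vertex object from its own single
projection:

```r
library(mirrorshape)
set.seed(1)
cam   <- camera(2)                          # F = (0, 0, 2), image plane z = 0
shape <- random_symmetric_pairs(8, cam)     # 8 mirror pairs, exact symmetry
cs    <- project_pairs(shape, cam)          # noiseless image correspondences
rec   <- recover_shape(cs, cam, d_c = shape$d_c)
rec
#> Recovered 3D mirror-symmetric shape: 8 pairs
#>   x_v = 4.86062, x_h = -0.82294, d_c = 3.07285, residual = 1.08e-15
max(abs(rec$P - shape$P), abs(rec$Q - shape$Q))
#> [1] 1.021405e-14
```

`x_v` is the vanishing-point abscissa of the symmetry-pair chords, `x_h`
the vanishing line of the symmetry plane, `residual` the RMS inconsistency
of the chords with a single vanishing point (here: exact), and the vertex
error shows the closed form inverting the projection to round-off.  With
the true `d_c` the recovery is exact; without it, `recover_shape(cs, cam)`
returns the deterministic unit-distance member of the similarity family.

The inverse-square worked example:

```r
inverse_square_fall(days(27.3), 3.84e8, 60)
#> $fall_at_orbit
#> [1] 0.001362411      # the Moon falls ~1.4e-3 m toward Earth in 1 s
#> $fall_scaled
#> [1] 4.90468          # scaled by 60^2: the Galilean 4.9 m surface fall
```

The shape-constancy experiment (symmetric polyhedron vs polygonal line,
200 trials per trial type, 90° view change, image noise 0.005):

```r
res <- run_experiment(classes = c("A", "C"), n_trials = 200,
                      sigma = 0.005, seed = 1)
res[, c("class", "hits", "false_alarms", "dprime", "ci_lower", "ci_upper")]
#>   class hits false_alarms dprime ci_lower ci_upper
#> 1     A  196           55 2.6515    2.210    3.093
#> 2     C  100           96 0.0502   -0.196    0.296
```

The symmetric polyhedron (class A) is discriminated reliably (d′ ≈ 2.7,
CI well above 0) while the polygonal line (class C), whose images admit no
consistent mirror interpretation, sits at chance — the qualitative
signature of symmetry-based shape constancy.

A thin command-line wrapper is installed at
`system.file("scripts", "mirrorshape", package = "mirrorshape")`, exposing
`simulate`, `project`, `recover`, `groups`, `noether-demo`, `experiment`
and `photometric` subcommands over the same functions.

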