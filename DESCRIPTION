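Package: mirrorshape
Title: Recovery of 3D Mirror-Symmetric Shapes from a Single Perspective
    Image, with Invariance and Constancy Toolkits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form recovery of 3D mirror-symmetric curves and
    polyhedra from a single 2D perspective image using the
    vanishing-point/vanishing-line construction, together with the
    symmetry-constrained energy functional and its maximum a posteriori
    reading, numerical verification suites for transformation-group
    axioms, the least-action principle and Noether conservation laws,
    simple lightness and von Kries color-constancy models, and a
    model-observer shape-constancy experiment analysed with signal
    detection theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
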