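Package: tubekin
Title: Covariant Tissue Kinematics on Folding Tubular Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of epithelial tissue deformation on
    evolving tube-like surfaces, as in the folding embryonic midgut.
    Provides discrete differential geometry on triangle meshes (mean
    curvature, covariant divergence, harmonic cylinder charts,
    centerlines), a test of incompressible surface kinematics
    (2*H*vn vs the covariant divergence of the tangential velocity),
    material-frame shear via the Beltrami coefficient, cell-shape
    tensors with area-weighted statistics and bootstrap standard
    errors, T1 neighbor-exchange detection, nuclei-pair relative
    motion, calcium-transient quantification from frame triplets, and
    two-sample comparison statistics. A synthetic-data generator
    produces area-preserving constricting-tube sequences, anisotropic
    cell tessellations, paired nuclei tracks, pulsed image movies and
    fold-outcome tables with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
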