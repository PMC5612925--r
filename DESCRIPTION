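Package: cardiomorph
Title: Geometric Morphometrics of Left-Ventricular Motion Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 4D statistical shape analysis of cyclic left-ventricular
    (LV) landmark motion. Provides Procrustes machinery (ordinary and
    generalized Procrustes alignment in size-and-shape space and shape space),
    cyclic temporal registration of cardiac cycles with a piecewise time warp
    and five-harmonic Fourier interpolation, Linear-Shift parallel transport of
    within-cycle deformations to the grand mean, principal-component ordination
    of transported deformations, phenotypic trajectory attributes (size,
    orientation and shape of the 30-frame path in PC space) with ANOVA, MANOVA
    and multivariate-dispersion group tests, repeated random-split support
    vector machine evaluation of morphometric and traditional indicators
    (EDV, ESV, EF), and a synthetic two-surface LV motion generator with
    volume ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'cardiomorph-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'linear_shift.R'
    'trajectory.R'
    'classification.R'
    'registration.R'
    'mesh.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
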