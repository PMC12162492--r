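Package: conebend
Title: Surface Strain, Profile Curvature and Arc-Bending Analysis of
    Hygroscopic Cone-Scale Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for the biomechanics of hygroscopic
    bending in conifer ovuliferous scales. Computes segment and planar
    principal strains between dry and wet states from digitized landmark
    correspondences (least-squares affine fit with polar decomposition),
    estimates profile curvature by chord-frame polynomial fitting and
    analytic differentiation, implements an analytic arc-bending laminate
    model relating adaxial/abaxial surface strains, lamina thickness and
    dry-state curvature, and derives morphometric indices (vascular-bundle
    position asymmetry, cell-wall density gradients) with the accompanying
    two-group statistics. Includes a synthetic-specimen generator with
    known ground truth so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
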