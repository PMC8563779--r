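Package: chainmorph
Title: Outline Morphometrics with Shape-Changing Kinematic Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a single chain of rigid (M), constant-curvature (C),
    constant-curvature-and-torsion helical (H), and scalable (G) segments to a
    family of 2D or 3D outline curves (open or closed), after resampling each
    outline into equal-length linear pieces. Homologous segmentation points are
    detected with the relative-angle (dominant point) method, supplementary
    points are placed by a genetic algorithm, and segment lengths are refined by
    two error-driven optimizers. Chain parameters (inter-segment orientation
    differences, piece-count length ratios, segment direction vectors) feed a
    stepwise linear discriminant analysis with leave-one-out cross-validation.
    Includes synthetic generators for chain-derived profile families, serrated
    leaf-like closed outlines, and smooth 3D suture-like curves so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: MASS, stats, utils, jsonlite, yaml, optparse
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
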