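Package: patchCT
Title: Few-View Tomography Reconstruction with Overlapping-Patch
    Dictionary Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative reconstruction of few-view parallel-beam computed
    tomography with a convex overlapping-patch dictionary-learning
    functional minimized by FISTA, including K-SVD dictionary training
    with orthogonal matching pursuit, filtered backprojection and
    total-variation baselines, a floating-solution comparison functional,
    a vectorial extension for differential phase-contrast tomography,
    structural-similarity quality metrics, and seeded synthetic phantom
    and sinogram generators for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
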