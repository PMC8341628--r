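Package: sporemorph
Title: Outline-Based Geometric Morphometrics of Fungal Spores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-free morphometric analysis of fungal spore
    silhouettes. Extracts Freeman chain-code outlines from binary
    micrographs, computes normalized elliptic Fourier descriptors,
    builds symmetric, asymmetric and global principal-component shape
    spaces, measures linear size traits (length, width, Q ratio,
    integrated size), and compares shape versus size descriptors for
    automated species identification with flexible discriminant
    analysis under repeated stratified cross-validation. Includes a
    generative model of bent-capsule spore silhouettes with hierarchical
    species/specimen/spore variation so the full pipeline can be
    exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    EBImage,
    png,
    yaml
Suggests:
    MASS,
    tiff,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
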