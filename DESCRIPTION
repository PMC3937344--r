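Package: mfaq
Title: Quantification Pipeline for the Molecular Force Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and quantifies Molecular Force Assay (MFA)
    experiments in which a protein-DNA bond is loaded in series with a
    DNA reference duplex until the weaker bond ruptures. Provides a
    Bell-model kinetic Monte Carlo and competing-hazards quadrature for
    the rupture competition, a seeded synthetic fluorescence image
    generator on the 4x4 pad layout, the Normalized Fluorescence (NF)
    pixel pipeline (background subtraction, pixel-by-pixel ratio,
    Gaussian histogram fits per pad), and the reference-length
    calibration that expresses protein-DNA binding strength in
    equivalent DNA base pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
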