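Package: phsi
Title: Polarized Hyperspectral Imaging Simulation and Stokes Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for full-Stokes polarized hyperspectral microscopy of the
    kind used to enhance collagen and cell visualization in stained pathology
    slides. Provides Mueller-calculus simulation of a dual liquid-crystal
    variable retarder (LCVR) analyzer train, synthetic birefringent-fiber and
    absorbing-cell phantoms with seeded noise, Stokes data-cube reconstruction
    from the four analyzer element images, rotating quarter-wave-plate
    calibration with RMSE validation, spectral-response-curve RGB synthesis,
    gray-level co-occurrence matrix (GLCM) contrast, masked region-of-interest
    spectral summaries, and per-band two-sample comparisons. Includes ENVI and
    multi-page TIFF cube input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
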