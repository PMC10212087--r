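Package: spheromech
Title: Microtweezer Stiffness Estimation and TEM Morphometry of Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the Young's modulus of multicellular tumor
    spheroids compressed between force-sensing micro-cantilevers (template
    matching of cantilever tips against a no-sample reference run, deflection
    to force conversion via the cantilever spring constant, and inversion of a
    sphere-between-plates Hertzian contact model), and to quantify transmission
    electron microscopy cross-section morphometry (cell and nucleus areas,
    complete-cell filtering, inner/outer region partition, and intercellular
    space density). A seeded synthetic-data module emulates both the
    compression image sequences and stitched TEM strips, with ground truth,
    so the full pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
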