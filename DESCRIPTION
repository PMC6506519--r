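Package: activedisc
Title: Active-Disc Segmentation of the Optic Disc and Cup with DDLS
    Glaucoma Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated glaucoma prescreening from color fundus
    photographs. Localizes the optic disc with a multiscale normalized
    matched filter, segments the optic disc and cup by fitting a
    two-concentric-circle active-disc template that minimizes a normalized
    contrast energy (evaluated by Green's-theorem boundary integrals and
    optimized by accelerated gradient descent), derives clinically relevant
    parameters (cup-to-disc ratio, rim-to-disc ratio, narrowest rim width,
    ISNT rim widths, rim-absence extent), and grades severity by the disc
    damage likelihood scale (DDLS) and the ICD-9 cup-to-disc rule. Includes
    a seeded synthetic-fundus generator with exact ground truth,
    segmentation evaluation metrics, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
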