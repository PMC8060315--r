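Package: ccsmorph
Title: 3D Morphometry of the Human Cardiac Conduction System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional morphometric analysis of the human
    cardiac conduction system (CCS) in a thoracic body-axis frame. Provides
    anatomical reference-axis extraction from named landmarks, rigid
    rotations about the sagittal, frontal and horizontal body axes,
    plane-projection angle measurement, bivariate regressions linking
    cardiac inclination to the inclinations of the sinus node and
    atrioventricular conduction axis, a stepwise standing-to-lying rotation
    simulation with concomitant/counter rotation classification, and a
    seeded synthetic-cohort generator that emulates the published
    morphometry of 23 cadaver hearts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
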