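Package: steppesim
Title: Spatially Explicit Functional-Group Simulation of Steppe Vegetation
    Dynamics Under Grazing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A grid-based, annual time-step simulator of plant functional
    group dynamics in temperate steppe and woodland-steppe landscapes under
    alternative grazing regimes. Plant cohorts progress through propagule,
    germinant, immature and mature stages; light competition acts through
    canopy strata; grazing acts through age-class-specific kill and resprout
    responses. Includes tools to process phytosociological releve tables
    (Braun-Blanquet cover codes), aggregate them to growth-form abundance
    matrices, derive landscape archetypes by k-means clustering with elbow
    selection, generate synthetic releve datasets for testing, and run full
    multi-landscape, multi-regime simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
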