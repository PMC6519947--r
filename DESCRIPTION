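Package: depotsim
Title: Transwell Release Simulation and Analysis for Liposome-Alginate
    Anesthetic Depots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of local-anesthetic transport from a
    liposome-alginate depot through a transwell insert into the bottom well
    of a culture plate, estimation of the depot's effective diffusivity from
    release measurements by sum-of-squares minimization, classification of
    release profiles against a cell-viability dose-response table, and 3D
    segmentation with spatial-uniformity statistics of liposome distribution
    in alginate microbeads imaged as confocal z-stacks. Includes seeded
    synthetic-data generators for release curves, bead z-stacks with
    ground-truth centroids, and replicate viability datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
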