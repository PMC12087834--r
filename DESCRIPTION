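Package: oculoshape
Title: Posterior Eye Shape Quantification from MRI Masks and Fundus Morphometry
Version: 0.1.0
Authors@R:
    person("Oculoshape", "Developers", email = "oculoshape@example.org",
           role = c("aut", "cre"))
Description: Quantifies three-dimensional posterior eye shape from binary MRI
    segmentation masks by ellipsoid fitting (principal component analysis of
    voxel coordinates), computing horizontal and vertical asphericity, volume,
    and goodness of fit, together with repeatability statistics (Dice overlap,
    intraclass correlation). Computes a twelve-feature fundus morphometry
    battery (optic disc and fovea geometry, Knudtson vessel calibre summaries,
    tortuosity, box-counting fractal dimension, arcade concavity, foveal pixel
    intensity) from geometric scene annotations with ocular magnification
    correction, and links features to asphericity with random-intercept linear
    mixed models that account for inter-eye correlation. Includes a seeded
    synthetic-data generator (voxelised rotated ellipsoids, fundus scenes with
    known ground truth, cohorts with known effect structure) so the whole
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
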