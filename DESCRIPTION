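Package: arraytomo
Title: Array Tomography Synapse Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of synapse density and pathological protein
    colocalization from array-tomography serial-section image stacks:
    rigid per-section registration, multi-algorithm automatic
    thresholding, 3D puncta reconstruction with single-section noise
    removal, amyloid plaque detection with near/far edge-distance
    classification, volumetric tau/amyloid-beta colocalization scoring,
    plaque burden and oligomeric-halo metrics, open-field trajectory zone
    metrics, and per-animal nonparametric statistics. Includes a
    calibrated synthetic-data generator with ground truth so the full
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
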