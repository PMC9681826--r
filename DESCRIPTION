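Package: paddyweed
Title: Weed Mapping in Rice Paddies from UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies weeds in flooded rice fields from five-band (blue,
    green, red, red-edge, near-infrared) unmanned-aerial-vehicle multispectral
    orthomosaics and turns the result into a gridded herbicide prescription
    map. Implements reflectance calibration against a reference panel, a
    log-ratio weed discrimination index family built on a cancelling transfer
    band, classical comparison indices (NDVI, GNDVI, NDRE, LCI, OSAVI),
    gray-level density slicing, majority-filter small-patch removal,
    clump (dilate-erode) smoothing, confusion-matrix and Cohen's kappa
    accuracy assessment with kernel-selection sweeps, raster-to-vector weed
    polygons, and resampling to a metric spray/no-spray grid. Includes a
    seeded synthetic paddy-scene generator so the full pipeline is testable
    without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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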