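Package: roadrisk
Title: Road-Risk Assessment for Apex Predators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A geospatial pipeline for assessing the risk posed by road
    networks to terrestrial apex predators. Computes per-species road
    exposure (square root of mean road density within the range) and a
    weighted vulnerability score (unprotected range fraction, IUCN status,
    threat count, body-mass class), combines them into a per-species road
    risk, builds a per-pixel cumulative road-risk surface with a
    protected-area term, and screens proposed road developments against it
    (impact levels per segment, species-range crossing lengths,
    protected-area intersections with a configurable buffer). Includes a
    data model for wildlife-vehicle-collision records with per-country and
    per-species summaries, and a seeded synthetic-world generator with
    closed-form ground truth so the whole pipeline is testable without
    external downloads. Rasters are exchanged as ESRI ASCII grids and
    vectors as GeoJSON; all lengths and areas are geodesic (WGS84).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    stats,
    tools,
    utils
Suggests:
    mgcv,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
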