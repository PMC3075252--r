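Package: geotracks
Title: Panbiogeographic Track Analysis from Species Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds individual panbiogeographic tracks as minimum spanning
    trees over georeferenced species occurrence records, detects spatial
    congruence between track segments with explicit geometric decision
    rules, merges congruent tracks into generalized tracks, reduces
    redundant tracks with an asymmetric length-based similarity index,
    and exports results as KML for display in common GIS viewers. Includes
    a synthetic corridor data generator with recovery scoring so the whole
    pipeline can be validated against data of known structure, and a
    command-line interface for batch analyses.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
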