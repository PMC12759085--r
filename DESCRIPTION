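Package: morphlineage
Title: Lineage Coupling, Track Decomposition and Neighbor Dynamics for
    Developing Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for time-resolved studies of developing
    tissues and explants. Builds cluster-level developmental lineage graphs
    from time-series single-cell embeddings by k-nearest-neighbor source-state
    assignment between adjacent timepoints; decomposes 3D cell tracks into a
    tissue-elongation component (derived from anchor cells) and per-cell
    migration trajectories; quantifies movement directions and
    radius-based neighbor retention between timepoints with one-way ANOVA
    group comparisons; and correlates cluster pseudo-bulk marker-gene
    profiles between a query dataset and a reference atlas. Ships seeded
    synthetic-data generators with known ground truth for every stage, plus
    readers and writers for the plain-text exchange formats (TSV, CSV,
    Matrix Market) and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
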