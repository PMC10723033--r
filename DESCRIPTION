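Package: spotlayer
Title: Layered Figure-Ground Spot Maps and Hexbin Summaries for 2D Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unified multi-dimensional 2D visualization for spatial
    transcriptomics spot maps and single-cell embeddings. Displays up to
    three variables per point in one static panel by layering aesthetics:
    a color fill (figure), a thin colored spot outline (ground), and an
    optional glyph (symbol). Also provides hexagonal binning of 2D
    embeddings with per-hexagon mean expression and majority cluster
    labels, and extraction of hexagon-edge region boundaries that replace
    overlapping convex-hull cluster annotations. Includes readers for
    delimited point tables, 10x Visium tissue positions and Matrix Market
    expression triplets, seeded synthetic-data generators with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
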