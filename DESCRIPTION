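Package: spices
Title: Particle-Based Molecular Line Notation and Simulation Box Start Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a SMILES-derived line notation describing
    particle-decomposed ("coarse-grained") molecules used in mesoscopic
    simulation techniques such as Dissipative Particle Dynamics. Provides a
    tokenizer, parser and validator with positional error diagnostics,
    serialization back to notation strings, topological queries (particle
    frequencies, neighbor shells, connected parts, double depth-first-search
    longest-chain determination with optional START/END orientation),
    conversion of molecule topologies to linear 3D tube geometries with
    side-chain collapse and uniform squeezing, population of simulation boxes
    with randomly placed or bilayer-oriented tubes, backbone-label driven
    force-index assignment, and reading/writing of the tabular ASCII particle
    records consumed by simulation kernels. Includes static DOT and GraphML
    graph export, reference fixture molecules (a DMPC phospholipid
    fragmentation and a fused-ring sterol analog) and a seeded random-molecule
    generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    xml2,
    withr,
    jsonlite
Config/testthat/edition: 3
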