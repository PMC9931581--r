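Package: spotcode
Title: Barcoded smFISH Simulation, Decoding and Spatial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for multiplexed, barcoded single-molecule FISH
    experiments in which RNA molecules are read out over cyclic
    hybridization rounds. Constructs constant-weight error-correcting
    barcode codebooks and decodes observed bit patterns; designs tiled
    encoding-probe panels under thermodynamic, composition, structure and
    specificity rules; simulates ground-truth tissue scenes and multi-round
    acquisitions; detects spots and registers rounds with fiducial beads;
    aggregates spots into molecules, estimates blank-based false-positive
    rates and assigns molecules to expanded segmentation masks; and
    provides spatial statistics including hexagonal-bin regionalization,
    border-strength fields, Ripley's L, lateral-diffusion profiling and
    optical-crowding simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    Biostrings,
    EBImage,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    spatial,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
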