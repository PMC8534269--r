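Package: lc3topo
Title: Back-Front Topology of Autophagy Compartments in Migrating Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial back-front organization of autophagy
    organelles (autophagosomes, autolysosomes, lysosomes) in single cells
    migrating on micro-patterned substrates. Implements organelle spot
    detection, object-based dual-channel (RFP-GFP-LC3 tandem reporter)
    classification, nucleus-anchored partitioning of the cell into ten
    front/back portions, per-portion density profiles and autophagy-flux
    indicators, nucleus-centroid motility metrics (speed, directionality
    ratio, direction autocorrelation), and per-portion group statistics.
    A deterministic synthetic time-lapse generator with ground truth makes
    every stage testable without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    data.table,
    graphics,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
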