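Package: beadFRET
Title: Solid-Support FRET High-Throughput Screening Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for solid-support FRET high-throughput
    screens of ribosome-bound nascent chain complexes (RNCs) immobilized
    on beads and imaged by high-content microscopy. Provides plate-layout
    modelling for 96/384/1,536-well paired donor and donor+acceptor
    designs, flat-field correction, bead segmentation with diameter,
    circularity and intensity gating, per-area fluorescence
    quantification, FRET efficiency by donor quenching, plate quality
    control and DMSO-baseline hit calling, Z-prime and plate summary
    statistics, four-parameter logistic dose-response fitting, and
    biochemical calculators for RNC concentration from scintillation
    counts, bead surface density, capture efficiency and geometric
    saturation. A forward simulator renders synthetic well images with
    known ground truth so every stage of the pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: CellBasedAssays, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
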