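Package: spectrinmesh
Title: Mechanical Network Modeling and Quantitative Imaging of the Spectrin
    Cortex
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the actin-spectrin membrane skeleton as a 2D network
    of spring and cable elements (spectrin tetramers, stress fibers, myosin
    linkers and rods) evolving under overdamped dynamics, with
    force-threshold detachment of compressed spectrin bundles and
    stochastic myosin turnover. Companion image-analysis operators
    implement quantitative microscopy procedures used to characterise
    spectrin meshwork organisation: top-quantile cluster segmentation,
    per-square-micrometre intensity distributions, structure-tensor
    orientation and coherency, nearest-neighbour distances, line-scan
    periodicity for expansion microscopy, inverted FRET ratio mapping,
    FRAP one-phase-association fitting, shifted cross-correlation, mask
    autocorrelation and normalized cluster area. A synthetic-data module
    generates images, FRET pairs, FRAP curves and time-lapses with known
    ground truth so that every operator can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    EBImage,
    minpack.lm,
    fitdistrplus,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
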