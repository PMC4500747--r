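Package: ephapse
Title: Microdomain Simulation of Ephaptic Cardiac Conduction and Perinexal
    Cluster Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying ephaptic (cleft-mediated) coupling in cardiac
    tissue. Implements a microdomain model of a two-dimensional sheet of
    three-dimensional myocytes with separable gap-junctional and extracellular
    cleft coupling, solved with linear finite elements inside each cell and a
    Crank-Nicolson time discretization; conduction-velocity and
    anisotropy-ratio quantification from activation maps; an object-based
    colocalization pipeline for two-channel super-resolution micrographs of
    connexin43 and Nav1.5 clusters (Otsu thresholding, connected-component
    labeling, edge-to-edge perinexal association); and synthetic-data
    generators for activation maps, upstroke traces, and cluster images so
    that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
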