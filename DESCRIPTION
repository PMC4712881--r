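Package: germsim
Title: Mechano-Logical Simulation of the C. elegans Germ Line
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3D agent-based simulator of Caenorhabditis elegans germline
    development and adult homeostasis. Germ cells are overlapping spheres moved
    by overdamped center-based mechanics inside a growing U-shaped gonad tube
    whose boundary follows the migrating distal tip cell (DTC). Cell fate is
    governed by per-cell hierarchical statecharts with orthogonal regions for
    the cell cycle, Notch (GLP-1) signalling, downstream GLD pathways and sex
    determination, including contact inhibition of the cell cycle under
    compression, distance-triggered meiotic entry and sperm/oocyte decisions,
    apoptosis of oogenic cells, and ovulation. The package provides lineage
    tracking, quantitative germline metrics (proliferative zone length, mitotic
    index, internuclear distance index), named experiment presets, and CSV/VTK
    snapshot output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
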