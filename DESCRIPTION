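Package: topomap
Title: Topological Model of Hippocampal Spatial Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hippocampal place-cell spiking during exploration of
    planar arenas with obstacles, converts spike trains into time-filtered
    coactivity and clique (cell-assembly) simplicial complexes, and uses
    simplicial homology over GF(2) -- including persistence over the
    first-appearance filtration -- to measure when, and whether, the neuronal
    ensemble encodes the topology of the environment. Includes theta-phase
    precession and gamma (Boltzmann-factor) spike modulation, cell-assembly
    selection, synaptic transmission/readout failure, transient ("flickering")
    coactivity complexes with lifetime and stability statistics, and
    parameter-scan drivers for learning-region, coactivity-window, and
    synaptic-criticality experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
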