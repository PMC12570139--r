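Package: allopath
Title: Allosteric Communication Paths from Dihedral Mutual Information in MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and ranks allosteric communication paths in protein
    molecular dynamics trajectories. Computes normalized mutual information
    (NMI) between per-residue phi-dihedral motions with histogram estimators,
    builds an NMI-weighted residue contact graph, traces maximum-cumulative-NMI
    routes between spatially distant residues with Dijkstra's algorithm,
    groups the top-ranked paths into distinct routes by hierarchical
    clustering with silhouette-based model selection, quantifies path
    stability by bootstrap resampling of trajectory frames, and exports
    viewer-ready spline geometry (PyMOL-style script, JSON, binary STL).
    Includes a synthetic-fixture generator that plants tunable dihedral
    correlations in small chain systems so the whole pipeline can be
    exercised without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    cluster,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
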