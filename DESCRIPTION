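Package: tunnelslicer
Title: Divide-and-Conquer Analysis of Protein Transport Tunnels in
    Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transport tunnels in multi-frame protein structures,
    analyses long trajectories slice by slice with globally continuous frame
    numbering, filters per-slice tunnel clusters by their relative presence,
    ranks and renumbers them by mean-throughput priority, and merges clusters
    from all slices into superclusters with Ward-linkage hierarchical
    clustering. Includes a grid-based Voronoi-style tunnel detector (Dijkstra
    minimum-cost pathways with probe-radius erosion), a CAVER-dialect cluster
    file format, a synthetic pseudo-protein shell generator with gated
    channels and exact ground truth, and utilities to compare sliced against
    full-trajectory runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
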