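Package: graphdist
Title: Graph Distance Measures and Two-Sample Comparison of Graph Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for comparing undirected graphs with six families of
    distance measures: spectral distances on the adjacency, combinatorial
    Laplacian and normalized Laplacian representations (with eigenvalue
    truncation and lp norms), the edit distance, the resistance-perturbation
    distance (exact, renormalized, and a closed form for single-edge
    perturbations), DeltaCon (fast belief propagation affinities compared by
    the Matusita difference), and the NetSimile feature-based distance.
    Includes random-graph ensembles (Erdos-Renyi, stochastic blockmodel,
    preferential attachment, Watts-Strogatz, configuration model, rectangular
    lattice) with connectivity conditioning and volume matching, a studentized
    distance-contrast protocol for two-sample testing of graph populations,
    temporal difference series for change-point detection in dynamic graphs,
    edgewise contrasts for populations of correlation matrices, and
    construction of connectome graphs from correlation matrices by
    thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    e1071,
    graphics,
    jsonlite,
    methods,
    withr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
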