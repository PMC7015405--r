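# Small fixture graphs built in code.

K3 <- igraph::make_full_graph(3)
P3 <- igraph::make_graph(~ A-B, B-C)
C6 <- igraph::make_ring(6)
star5 <- igraph::make_star(5, mode = "undirected", center = 1)

# an asymmetric 5-vertex tree (no nontrivial automorphisms)
asym_tree <- igraph::make_graph(~ a-b, b-c, c-d, b-e)

weighted_edge <- function() {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  g <- igraph::add_edges(g, c(1, 2))
  igraph::E(g)$weight <- 2.5
  g
}

random_connected_gnp <- function(n, p, seed = NULL) {
  sample_graph(ensemble_spec("er", n = n, p = p, require_connected = TRUE),
               seed = seed)
}

edge_key_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
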