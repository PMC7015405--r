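# NetSimile: per-vertex egonet features, aggregated into a fixed-length
# signature per graph, signatures compared with the Canberra distance.
# Graphs are treated as unweighted (any positive weight counts as an edge).

NETSIMILE_FEATURES <- c(
  "degree",
  "clustering",
  "mean_neighbor_degree",
  "mean_neighbor_clustering",
  "egonet_edges",
  "egonet_outgoing_edges",
  "egonet_neighbors"
)

NETSIMILE_STATS <- c("mean", "median", "sd", "skewness", "kurtosis")

#' Per-vertex NetSimile features
#'
#' Computes, for every vertex i, the seven local/egonet features on the
#' binarized graph: (1) degree; (2) local clustering coefficient; (3) mean
#' degree of i's neighbors; (4) mean clustering coefficient of i's
#' neighbors; (5) number of edges in i's egonet (i, its neighbors, and all
#' edges among them); (6) number of edges leaving the egonet; (7) number of
#' distinct vertices outside the egonet adjacent to it. Degenerate cases
#' (isolated vertices, degree below 2) yield 0 for the affected features.
#'
#' @inheritParams graph_degrees
#' @return A 7 x n numeric matrix, rows named by feature.
#' @export
#' @examples
#' netsimile_features(igraph::make_full_graph(3))[, 1]  # 2 1 2 1 3 0 0
netsimile_features <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  A <- matrix_representation(g, "adjacency")
  A[A > 0] <- 1                                # binarize
  d <- colSums(A)
  # triangles through i = edges among i's neighbors = (A^3)_ii / 2
  A2 <- A %*% A
  tri <- colSums(A2 * A) / 2
  denom <- d * (d - 1) / 2
  clust <- ifelse(denom > 0, tri / denom, 0)
  nbr_deg <- ifelse(d > 0, as.numeric(A %*% d) / d, 0)
  nbr_clust <- ifelse(d > 0, as.numeric(A %*% clust) / d, 0)
  ego_edges <- d + tri
  # edges leaving the egonet: total degree of egonet members minus twice
  # the edges inside it
  M <- A + diag(n)                             # closed-neighborhood indicator
  ego_degree_sum <- as.numeric(t(M) %*% d)
  ego_out <- ego_degree_sum - 2 * ego_edges
  # distinct outside vertices adjacent to the egonet
  reach <- (A %*% M) > 0                       # reach[u, i]: u adjacent to N[i]
  ego_nbrs <- colSums(reach & (M == 0))
  out <- rbind(d, clust, nbr_deg, nbr_clust, ego_edges, ego_out, ego_nbrs)
  rownames(out) <- NETSIMILE_FEATURES
  colnames(out) <- NULL
  out
}

# moment-based skewness (g1) and excess kurtosis (g2); constant vectors
# map to 0 so regular graphs have finite signatures
safe_moment <- function(x, fun) {
  v <- suppressWarnings(fun(x))
  if (!is.finite(v)) 0 else v
}

#' NetSimile signature vector
#'
#' Aggregates the 7 x n feature matrix into a length-35 signature: for each
#' feature, the mean, median, sample standard deviation, moment skewness,
#' and excess kurtosis across vertices (in that order). Constant feature
#' rows get 0 for sd, skewness, and kurtosis. The signature depends only on
#' the multiset of per-vertex features, so it is invariant under vertex
#' relabelling, and graphs of different sizes can be compared.
#'
#' @inheritParams graph_degrees
#' @return A named numeric vector of length 35.
#' @export
netsimile_signature <- function(g) {
  f <- netsimile_features(g)
  sig <- apply(f, 1, function(x) {
    s <- stats::sd(x)
    c(mean(x),
      stats::median(x),
      if (is.finite(s)) s else 0,
      safe_moment(x, function(z) e1071::skewness(z, type = 1)),
      safe_moment(x, function(z) e1071::kurtosis(z, type = 1)))
  })
  out <- as.numeric(sig)
  names(out) <- paste(rep(rownames(f), each = length(NETSIMILE_STATS)),
                      NETSIMILE_STATS, sep = "_")
  out[!is.finite(out)] <- 0
  out
}

# Canberra distance with the |x| + |y| denominator and 0/0 terms dropped.
canberra <- function(x, y) {
  num <- abs(x - y)
  den <- abs(x) + abs(y)
  sum(ifelse(den > 0, num / den, 0))
}

#' NetSimile distance
#'
#' Canberra distance between the NetSimile signature vectors of the two
#' graphs. Because signatures have fixed length the graphs may have
#' different sizes, and the distance is invariant under vertex relabelling
#' of either graph.
#'
#' @inheritParams graph_degrees
#' @param h A second graph.
#' @return A nonnegative number.
#' @export
netsimile_distance <- function(g, h) {
  canberra(netsimile_signature(g), netsimile_signature(h))
}
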