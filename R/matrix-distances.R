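# Matrix distances compare node-affinity matrices entrywise and therefore
# require a node correspondence between the two graphs: vertex i of g is
# assumed to be the same actor as vertex i of h.

# Entrywise l1 norm over the full (ordered-pair) matrix. Each undirected
# edge discrepancy is counted twice, matching the double sum over i, j.
entrywise_l1 <- function(M) sum(abs(M))

require_same_size <- function(g, h, what) {
  ng <- igraph::vcount(g); nh <- igraph::vcount(h)
  if (ng != nh) {
    stop(what, " requires node correspondence: graphs must have the same ",
         "vertex count (got ", ng, " and ", nh, ")", call. = FALSE)
  }
  invisible(ng)
}

#' Edit distance
#'
#' The entrywise l1 norm of the difference of the two (weighted) adjacency
#' matrices, summed over all ordered vertex pairs, so each undirected edge
#' discrepancy contributes twice. For unweighted graphs this is twice the
#' size of the symmetric difference of the edge sets. Requires node
#' correspondence (same vertex count, matched by index).
#'
#' @param g,h Undirected simple igraph objects on the same vertex set.
#' @return A nonnegative number.
#' @export
#' @examples
#' edit_distance(igraph::make_full_graph(3),
#'               igraph::make_graph(~ 1-2, 2-3))  # 2
edit_distance <- function(g, h) {
  check_graph(g); check_graph(h)
  require_same_size(g, h, "edit distance")
  A <- matrix_representation(g, "adjacency")
  B <- matrix_representation(h, "adjacency")
  entrywise_l1(A - B)
}

#' Effective resistance matrix
#'
#' The effective graph resistance `R(u, v)` treats each edge as a resistor
#' of conductance equal to its weight and measures the electrical
#' resistance between every vertex pair:
#' `R(u, v) = Ldag[u,u] + Ldag[v,v] - 2 Ldag[u,v]`, with `Ldag` the
#' Moore-Penrose pseudoinverse of the combinatorial Laplacian. Unlike the
#' shortest-path distance it is sensitive to all paths between a pair, and
#' it is a metric on the vertex set. Defined only for connected graphs; see
#' [renormalized_resistance_matrix()] for the disconnected extension.
#'
#' @inheritParams graph_degrees
#' @return A symmetric n x n matrix with zero diagonal.
#' @export
#' @examples
#' resistance_matrix(igraph::make_full_graph(3))  # off-diagonals 2/3
resistance_matrix <- function(g) {
  check_graph(g)
  if (!igraph::is_connected(g)) {
    stop("effective resistance is undefined for disconnected graphs; ",
         "use renormalized_resistance_matrix()", call. = FALSE)
  }
  L <- matrix_representation(g, "laplacian")
  n <- nrow(L)
  # For connected graphs the pseudoinverse is solve(L + J/n) - J/n.
  Ldag <- solve(L + 1 / n) - 1 / n
  d <- diag(Ldag)
  R <- outer(d, d, "+") - 2 * Ldag
  diag(R) <- 0
  pmax((R + t(R)) / 2, 0)
}

#' Renormalized resistance matrix
#'
#' A bounded transform of the effective resistance that stays defined on
#' disconnected graphs: within a connected component
#' `rho(u, v) = R(u, v) / (1 + R(u, v))`, and `rho(u, v) = 1` for vertices
#' in different components (the limit of the transform as R grows without
#' bound). Entries lie in `[0, 1]`; the map is strictly monotone in R, so
#' the ordering of pairwise affinities within a component is preserved.
#'
#' @inheritParams graph_degrees
#' @return A symmetric n x n matrix with zero diagonal and entries in
#'   `[0, 1]`.
#' @export
renormalized_resistance_matrix <- function(g) {
  check_graph(g)
  n <- igraph::vcount(g)
  comp <- igraph::components(g)
  rho <- matrix(1, n, n)
  for (c_id in seq_len(comp$no)) {
    idx <- which(comp$membership == c_id)
    if (length(idx) == 1) {
      rho[idx, idx] <- 0
      next
    }
    sub <- igraph::induced_subgraph(g, idx)
    R <- resistance_matrix(sub)
    rho[idx, idx] <- R / (1 + R)
  }
  diag(rho) <- 0
  rho
}

#' Resistance-perturbation distance
#'
#' The entrywise l1 norm of the difference between the effective resistance
#' matrices of two graphs on a common vertex set (summed over ordered
#' pairs). The distance is designed to detect changes in large-scale
#' connectivity while remaining insensitive to local edge churn that does
#' not alter how well regions of the graph communicate. With
#' `renormalized = TRUE` the bounded renormalized resistance matrices are
#' compared instead, which extends the distance to disconnected graphs.
#'
#' @inheritParams edit_distance
#' @param renormalized Use the renormalized resistance (allows
#'   disconnected inputs). Default `FALSE`.
#' @return A nonnegative number.
#' @export
#' @examples
#' resistance_distance(igraph::make_graph(~ 1-2, 2-3),
#'                     igraph::make_full_graph(3))  # 4
resistance_distance <- function(g, h, renormalized = FALSE) {
  check_graph(g); check_graph(h)
  require_same_size(g, h, "resistance distance")
  if (renormalized) {
    Rg <- renormalized_resistance_matrix(g)
    Rh <- renormalized_resistance_matrix(h)
  } else {
    Rg <- resistance_matrix(g)
    Rh <- resistance_matrix(h)
  }
  entrywise_l1(Rg - Rh)
}

#' Fast belief propagation affinity matrix
#'
#' The node-affinity matrix `S = [I + eps^2 D - eps A]^{-1}` underlying
#' DeltaCon. Its power-series expansion
#' `S = I + eps A + eps^2 (A^2 - D) + O(eps^3)` shows that it weights
#' neighbors at path length k by `eps^k`, blending local and global
#' structure. Computed by an exact dense solve.
#'
#' @inheritParams graph_degrees
#' @param epsilon Positive scalar; see [deltacon()] for the default used
#'   there.
#' @return A symmetric n x n matrix.
#' @export
fbp_matrix <- function(g, epsilon) {
  check_graph(g)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) ||
      epsilon < 0) {
    stop("`epsilon` must be a single nonnegative number", call. = FALSE)
  }
  A <- matrix_representation(g, "adjacency")
  d <- graph_degrees(g)
  n <- nrow(A)
  M <- diag(1 + epsilon^2 * d, nrow = n) - epsilon * A
  S <- tryCatch(solve(M), error = function(e) {
    stop("fast belief propagation system is singular; reduce `epsilon`",
         call. = FALSE)
  })
  (S + t(S)) / 2
}

# DeltaCon's epsilon convention: 1 / (1 + max degree).
deltacon_epsilon <- function(g, h) 1 / (1 + max(graph_degrees(g), graph_degrees(h)))

#' DeltaCon distance
#'
#' Compares the fast belief propagation affinity matrices S and S' of the
#' two graphs (computed with a common `epsilon`) via the Matusita
#' difference, `sqrt(sum((sqrt(S) - sqrt(S'))^2))`. Tiny negative entries
#' of S (possible numerically for large `epsilon`) are clamped to zero
#' before the square root. The radical-free variant
#' `sum((S - S')^2)` is available as `variant = "printed"`.
#'
#' @inheritParams edit_distance
#' @param epsilon Affinity decay parameter; default `1 / (1 + max degree)`
#'   over both graphs.
#' @param variant `"matusita"` (default) or `"printed"`.
#' @return A nonnegative number.
#' @export
deltacon <- function(g, h, epsilon = NULL, variant = c("matusita", "printed")) {
  check_graph(g); check_graph(h)
  variant <- match.arg(variant)
  require_same_size(g, h, "DeltaCon")
  if (is.null(epsilon)) epsilon <- deltacon_epsilon(g, h)
  Sg <- fbp_matrix(g, epsilon)
  Sh <- fbp_matrix(h, epsilon)
  if (variant == "printed") {
    return(sum((Sg - Sh)^2))
  }
  sqrt(sum((sqrt(pmax(Sg, 0)) - sqrt(pmax(Sh, 0)))^2))
}

#' Closed-form resistance-perturbation distance for a single edge change
#'
#' For a connected graph `G` and a weight perturbation `delta_w` on the
#' single vertex pair `(i, j)` (adding a new edge, or changing/removing an
#' existing one), the resistance-perturbation distance between `G` and the
#' perturbed graph has the closed form
#' \deqn{2 n \frac{|\Delta w|}{1 + \Delta w R_{ij}}
#'       \sum_{k \ge 2} \frac{(\phi_k(i) - \phi_k(j))^2}{\lambda_k^2},}
#' where `lambda_k`, `phi_k` are the eigenvalues (ascending) and
#' orthonormal eigenvectors of the combinatorial Laplacian of `G` and
#' `R_{ij}` its effective resistance between `i` and `j`. The sum is the
#' graph's "frequency response" to the perturbation: slow modes (small
#' `lambda_k`) dominate when `i` and `j` straddle weakly connected regions,
#' which is why the distance highlights inter-community changes.
#'
#' The combinatorial-Laplacian eigendecomposition is the convention that
#' reproduces the direct recomputation `resistance_distance(g, g')` (they
#' agree to relative error below 1e-6); it follows from a rank-one
#' Sherman-Morrison update of the Laplacian pseudoinverse.
#'
#' @inheritParams graph_degrees
#' @param i,j Distinct vertex indices in `1:vcount(g)`.
#' @param delta_w Weight change; the resulting weight `w_ij + delta_w` must
#'   be nonnegative, and the perturbation must not disconnect the graph.
#' @return A nonnegative number.
#' @export
rp_single_edge <- function(g, i, j, delta_w) {
  check_graph(g)
  n <- igraph::vcount(g)
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(c(i, j)) || i < 1 || j < 1 || i > n || j > n || i == j) {
    stop("`i` and `j` must be distinct vertices of `g`", call. = FALSE)
  }
  if (!igraph::is_connected(g)) {
    stop("`g` must be connected", call. = FALSE)
  }
  eid <- igraph::get_edge_ids(g, c(i, j))
  w_cur <- if (eid > 0) edge_weights(g)[eid] else 0
  if (w_cur + delta_w < -1e-12) {
    stop("perturbed weight would be negative", call. = FALSE)
  }
  if (delta_w == 0) return(0)
  L <- matrix_representation(g, "laplacian")
  ed <- eigen(L, symmetric = TRUE)
  lambda <- rev(ed$values)                     # ascending
  phi <- ed$vectors[, rev(seq_len(n)), drop = FALSE]
  dphi2 <- (phi[i, ] - phi[j, ])^2
  keep <- lambda > 1e-10 * max(lambda)
  R_ij <- sum(dphi2[keep] / lambda[keep])
  denom <- 1 + delta_w * R_ij
  if (denom <= 1e-12) {
    stop("perturbation removes a bridge and disconnects the graph; the ",
         "resistance distance to the perturbed graph is undefined",
         call. = FALSE)
  }
  response <- sum(dphi2[keep] / lambda[keep]^2)
  2 * n * abs(delta_w) / denom * response
}

#' Apply a single-edge weight perturbation
#'
#' Returns the graph obtained from `g` by adding `delta_w` to the weight of
#' the vertex pair `(i, j)` (creating or deleting the edge as needed).
#' Companion to [rp_single_edge()] and useful for oracle checks.
#'
#' @inheritParams rp_single_edge
#' @return An igraph object.
#' @export
perturb_edge <- function(g, i, j, delta_w) {
  check_graph(g)
  A <- matrix_representation(g, "adjacency")
  w_new <- A[i, j] + delta_w
  if (w_new < -1e-12) stop("perturbed weight would be negative", call. = FALSE)
  if (w_new < 1e-15) w_new <- 0
  A[i, j] <- w_new
  A[j, i] <- w_new
  out <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
  if (all(edge_weights(out) == 1)) out <- igraph::delete_edge_attr(out, "weight")
  check_graph(out)
}
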