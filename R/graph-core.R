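#' @importFrom stats median quantile rnorm sd setNames
#' @importFrom utils head
NULL

# Internal: validate an igraph object against the package's graph model
# (undirected, simple, no self-loops, strictly positive weights if weighted).
# Returns the graph invisibly so it can be used in pipelines.
check_graph <- function(g, arg = deparse(substitute(g))) {
  if (!igraph::is_igraph(g)) {
    stop(sprintf("`%s` must be an igraph object", arg), call. = FALSE)
  }
  if (igraph::is_directed(g)) {
    stop(sprintf("`%s` must be undirected", arg), call. = FALSE)
  }
  if (igraph::any_loop(g)) {
    stop(sprintf("`%s` must not contain self-loops", arg), call. = FALSE)
  }
  if (igraph::any_multiple(g)) {
    stop(sprintf("`%s` must be a simple graph (no multi-edges)", arg), call. = FALSE)
  }
  w <- igraph::E(g)$weight
  if (!is.null(w)) {
    if (anyNA(w) || any(w <= 0)) {
      stop(sprintf("`%s` has non-positive or missing edge weights", arg),
           call. = FALSE)
    }
  }
  invisible(g)
}

# Internal: edge weights, defaulting to 1 for unweighted graphs.
edge_weights <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) rep(1, igraph::ecount(g)) else w
}

#' Weighted vertex degrees
#'
#' The degree of a vertex is the sum of the weights of its incident edges;
#' for unweighted graphs this is the usual edge count. Isolated vertices
#' have degree 0.
#'
#' @param g An undirected simple igraph object, optionally with a positive
#'   `weight` edge attribute.
#' @return Numeric vector of length `vcount(g)`.
#' @export
#' @examples
#' graph_degrees(igraph::make_full_graph(3))
graph_degrees <- function(g) {
  check_graph(g)
  as.numeric(igraph::strength(g, weights = edge_weights(g)))
}

#' Matrix representations of a graph
#'
#' Builds one of the three symmetric matrix representations used throughout
#' the package: the (weighted) adjacency matrix A, the combinatorial
#' Laplacian L = D - A, or the normalized Laplacian D^{-1/2} L D^{-1/2},
#' where D is the diagonal matrix of (weighted) degrees. For vertices of
#' degree zero the corresponding entry of D^{-1/2} is set to 0, so isolated
#' vertices contribute an all-zero row and column to the normalized
#' Laplacian.
#'
#' @inheritParams graph_degrees
#' @param kind One of `"adjacency"`, `"laplacian"`, `"normalized_laplacian"`.
#' @return A dense symmetric numeric matrix of dimension n x n.
#' @export
#' @examples
#' matrix_representation(igraph::make_full_graph(3), "laplacian")
matrix_representation <- function(g,
                                  kind = c("adjacency", "laplacian",
                                           "normalized_laplacian")) {
  check_graph(g)
  kind <- match.arg(kind)
  w <- edge_weights(g)
  attr_name <- if (is.null(igraph::E(g)$weight)) NULL else "weight"
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = attr_name, sparse = TRUE))
  storage.mode(A) <- "double"
  dimnames(A) <- NULL
  if (kind == "adjacency") {
    return(A)
  }
  d <- as.numeric(igraph::strength(g, weights = w))
  L <- diag(d, nrow = nrow(A)) - A
  if (kind == "laplacian") {
    return(L)
  }
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  NL <- L * outer(dinv, dinv)
  (NL + t(NL)) / 2
}

#' Graph volume
#'
#' The volume of a graph is its number of edges for unweighted graphs, and
#' the total edge weight for weighted graphs.
#'
#' @inheritParams graph_degrees
#' @return A nonnegative number.
#' @export
graph_volume <- function(g) {
  check_graph(g)
  sum(edge_weights(g))
}

#' Connected components
#'
#' @inheritParams graph_degrees
#' @return A list with `count` (number of components) and `labels`
#'   (integer membership vector of length n, values in `1:count`).
#' @export
graph_components <- function(g) {
  check_graph(g)
  comp <- igraph::components(g)
  list(count = comp$no, labels = as.integer(comp$membership))
}

#' Relabel vertices by a permutation
#'
#' Returns the isomorphic graph whose adjacency matrix is P' A P for the
#' permutation matrix P encoded by `perm`: vertex `i` of `g` becomes vertex
#' `perm[i]` of the result. Edge weights travel with the edges.
#'
#' @inheritParams graph_degrees
#' @param perm An integer vector: a permutation of `1:vcount(g)`.
#' @return An igraph object isomorphic to `g`.
#' @export
permute_graph <- function(g, perm) {
  check_graph(g)
  n <- igraph::vcount(g)
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n))) {
    stop("`perm` must be a permutation of 1:vcount(g)", call. = FALSE)
  }
  igraph::permute(g, perm)
}

#' Read and write edge-list graph files
#'
#' The edge-list format is plain text: one edge per line as
#' `i j` or `i j w` with whitespace separation, 0-based integer vertex
#' indices, and an optional strictly positive weight. Lines starting with
#' `#` are comments; the writer emits a `# n <vertex count>` header so
#' isolated trailing vertices survive a round trip. Invalid content
#' (self-loop, negative or zero weight, duplicate edge with a conflicting
#' weight, out-of-range index) is rejected with the offending line number.
#'
#' @param path Path to the file.
#' @param n Optional vertex count override when reading; by default the
#'   `# n` header or the largest index seen determines it.
#' @return `read_edge_list` returns an igraph object; `write_edge_list`
#'   returns `path` invisibly.
#' @export
read_edge_list <- function(path, n = NULL) {
  lines <- readLines(path)
  header_n <- NULL
  from <- integer(0); to <- integer(0); w <- numeric(0)
  seen <- new.env(parent = emptyenv())
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (nzchar(raw) && startsWith(raw, "#")) {
      m <- regmatches(raw, regexec("^#\\s*n\\s+(\\d+)\\s*$", raw))[[1]]
      if (length(m) == 2) header_n <- as.integer(m[[2]])
      next
    }
    if (!nzchar(raw)) next
    parts <- strsplit(raw, "\\s+")[[1]]
    if (!length(parts) %in% c(2, 3)) {
      stop(sprintf("line %d: expected 'i j [w]', got %s", ln, sQuote(raw)),
           call. = FALSE)
    }
    i <- suppressWarnings(as.integer(parts[[1]]))
    j <- suppressWarnings(as.integer(parts[[2]]))
    if (is.na(i) || is.na(j) || i < 0 || j < 0) {
      stop(sprintf("line %d: vertex indices must be nonnegative integers", ln),
           call. = FALSE)
    }
    if (i == j) {
      stop(sprintf("line %d: self-loop (%d, %d) is not allowed", ln, i, j),
           call. = FALSE)
    }
    wt <- if (length(parts) == 3) suppressWarnings(as.numeric(parts[[3]])) else 1
    if (is.na(wt) || wt <= 0) {
      stop(sprintf("line %d: edge weight must be a positive number", ln),
           call. = FALSE)
    }
    key <- paste(min(i, j), max(i, j))
    prev <- get0(key, envir = seen)
    if (!is.null(prev)) {
      if (prev != wt) {
        stop(sprintf("line %d: duplicate edge (%d, %d) with conflicting weight",
                     ln, i, j), call. = FALSE)
      }
      next
    }
    assign(key, wt, envir = seen)
    from <- c(from, i); to <- c(to, j); w <- c(w, wt)
  }
  declared <- if (!is.null(n)) n else header_n
  n_seen <- if (length(from)) max(from, to) + 1L else 0L
  if (!is.null(declared) && n_seen > declared) {
    stop("vertex index out of range for the declared vertex count (n = ",
         declared, ")", call. = FALSE)
  }
  n_eff <- max(c(declared, n_seen, 0L))
  g <- igraph::make_empty_graph(n = n_eff, directed = FALSE)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from + 1L, to + 1L))
    if (any(w != 1)) igraph::E(g)$weight <- w
  }
  check_graph(g)
}

#' @rdname read_edge_list
#' @inheritParams graph_degrees
#' @export
write_edge_list <- function(g, path) {
  check_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  w <- igraph::E(g)$weight
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n %d", igraph::vcount(g)), con)
  if (nrow(el)) {
    if (is.null(w)) {
      writeLines(sprintf("%d %d", el[, 1], el[, 2]), con)
    } else {
      writeLines(sprintf("%d %d %.17g", el[, 1], el[, 2], w), con)
    }
  }
  invisible(path)
}

#' Read and write graphs as Matrix Market symmetric adjacency matrices
#'
#' Adjacency matrices are exchanged in Matrix Market coordinate format
#' (`%%MatrixMarket matrix coordinate real symmetric`), the standard sparse
#' interchange format. Only the lower triangle is stored; the matrix
#' dimension fixes the vertex count, so isolated vertices round-trip.
#'
#' @param path Path to the `.mtx` file.
#' @return `read_adjacency` returns an igraph object; `write_adjacency`
#'   returns `path` invisibly.
#' @export
read_adjacency <- function(path) {
  M <- Matrix::readMM(path)
  M <- methods::as(M, "CsparseMatrix")
  M <- Matrix::forceSymmetric(M, uplo = "L")
  if (any(Matrix::diag(M) != 0)) {
    stop("adjacency matrix must have a zero diagonal (no self-loops)",
         call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                           weighted = TRUE)
  if (all(edge_weights(g) == 1)) g <- igraph::delete_edge_attr(g, "weight")
  check_graph(g)
}

#' @rdname read_adjacency
#' @inheritParams graph_degrees
#' @export
write_adjacency <- function(g, path) {
  check_graph(g)
  attr_name <- if (is.null(igraph::E(g)$weight)) NULL else "weight"
  A <- igraph::as_adjacency_matrix(g, attr = attr_name, sparse = TRUE)
  Matrix::writeMM(methods::as(Matrix::forceSymmetric(A, uplo = "L"),
                              "generalMatrix"), path)
  invisible(path)
}

#' Build a connectome graph from a correlation matrix
#'
#' Thresholds a region-by-region correlation matrix (e.g. 116 x 116 for an
#' anatomical brain atlas) into a graph: an edge joins regions `u` and `v`
#' whenever `|rho(u, v)| >= T`. In `"weighted"` mode the edge weight is
#' `|rho(u, v)|`; in `"binary"` mode it is 1. Low correlations are excluded
#' because they are typically spurious. The diagonal is ignored (no
#' self-loops) and all regions are retained as vertices, connected or not.
#'
#' @param rho Symmetric numeric matrix with unit diagonal and entries in
#'   `[-1, 1]`.
#' @param T Threshold in `[0, 1]`.
#' @param mode `"weighted"` or `"binary"`.
#' @return An igraph object on `nrow(rho)` vertices.
#' @export
threshold_correlation <- function(rho, T, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) {
    stop("`rho` must be a square matrix", call. = FALSE)
  }
  if (max(abs(rho - t(rho))) > 1e-10) {
    stop("`rho` must be symmetric", call. = FALSE)
  }
  if (any(abs(rho) > 1 + 1e-10) || max(abs(diag(rho) - 1)) > 1e-10) {
    stop("`rho` must have unit diagonal and entries in [-1, 1]", call. = FALSE)
  }
  if (!is.numeric(T) || length(T) != 1 || is.na(T) || T < 0 || T > 1) {
    stop("`T` must be a single number in [0, 1]", call. = FALSE)
  }
  n <- nrow(rho)
  W <- abs(rho)
  diag(W) <- 0
  W[W < T] <- 0
  if (mode == "binary") W[W > 0] <- 1
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  if (mode == "binary" || all(edge_weights(g) == 1)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  check_graph(g)
}
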