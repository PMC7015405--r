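# Eigenvalue orderings follow the conventions used for truncated spectral
# comparison: the adjacency spectrum is kept in descending order (largest
# eigenvalues first), the Laplacian spectra in ascending order (smallest
# first), so the leading k entries are always the k that a truncated
# distance compares.

SPECTRUM_KINDS <- c("adjacency", "laplacian", "normalized_laplacian")

# Dense symmetric eigensolve guard; the package targets graphs up to a few
# thousand vertices, where full LAPACK decomposition is exact and fast.
DENSE_EIG_GUARD <- 5000L

#' Graph spectrum
#'
#' Computes the eigenvalues of a matrix representation of a graph, ordered
#' by the convention of the corresponding spectral distance: descending for
#' the adjacency matrix, ascending for the combinatorial and normalized
#' Laplacians. With `k` supplied only the leading `k` eigenvalues are
#' retained (the `k` largest for the adjacency, the `k` smallest for the
#' Laplacians).
#'
#' @inheritParams matrix_representation
#' @param k Optional number of eigenvalues to retain, `1 <= k <= vcount(g)`.
#' @return An object of class `graph_spectrum`: a list with `values`,
#'   `kind`, `k`, and `n`.
#' @export
#' @examples
#' graph_spectrum(igraph::make_full_graph(3), "adjacency")$values  # 2, -1, -1
graph_spectrum <- function(g, kind = SPECTRUM_KINDS, k = NULL) {
  check_graph(g)
  kind <- match.arg(kind)
  n <- igraph::vcount(g)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (length(k) != 1 || is.na(k) || k < 1 || k > n) {
      stop("`k` must be an integer in [1, vcount(g)]", call. = FALSE)
    }
  }
  if (n > DENSE_EIG_GUARD) {
    warning("dense eigendecomposition on a graph with n > ", DENSE_EIG_GUARD,
            " vertices; expect this to be slow", call. = FALSE)
  }
  M <- matrix_representation(g, kind)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values  # descending
  if (kind != "adjacency") ev <- rev(ev)                       # ascending
  if (!is.null(k)) ev <- ev[seq_len(k)]
  structure(list(values = as.numeric(ev), kind = kind,
                 k = if (is.null(k)) length(ev) else k, n = n),
            class = "graph_spectrum")
}

#' @export
print.graph_spectrum <- function(x, ...) {
  cat(sprintf("<graph_spectrum> kind=%s, k=%d of n=%d\n", x$kind, x$k, x$n))
  print(utils::head(x$values, 10))
  if (x$k > 10) cat("...\n")
  invisible(x)
}

# lp norm of a difference vector, with the conventions used for spectral
# comparison: p = 0 counts entries differing beyond tolerance, p = Inf is
# the maximum absolute difference, 0 < p < 1 is computed but is not a true
# metric (warned about once per call).
lp_norm <- function(x, p, tol = 1e-8) {
  if (p == 0) return(sum(abs(x) > tol))
  if (is.infinite(p)) return(max(abs(x), 0))
  if (p < 1) {
    warning("lp 'norms' with p < 1 are not true metrics (triangle inequality fails)",
            call. = FALSE)
  }
  sum(abs(x)^p)^(1 / p)
}

#' Spectral distance between two graphs
#'
#' The lp distance between the (possibly truncated) spectra of the chosen
#' matrix representation of `g` and `h`. Eigenvalues are paired by rank
#' after sorting per the representation's convention, so no vertex
#' correspondence between the graphs is needed, and the distance is
#' invariant under vertex relabelling. Graphs of different sizes can only
#' be compared with an explicit truncation `k <= min(n, n')`.
#'
#' Spectral distances are pseudometrics: cospectral non-isomorphic graphs
#' are at distance 0.
#'
#' @param g,h Undirected simple igraph objects.
#' @inheritParams graph_spectrum
#' @param p Norm order in `[0, Inf]`; default 2. `p = 0` counts differing
#'   eigenvalues, `p = Inf` takes the largest difference.
#' @return A nonnegative number.
#' @export
#' @examples
#' spectral_distance(igraph::make_ring(3), igraph::make_star(3, "undirected"))
spectral_distance <- function(g, h, kind = SPECTRUM_KINDS, k = NULL, p = 2) {
  kind <- match.arg(kind)
  check_graph(g); check_graph(h)
  ng <- igraph::vcount(g); nh <- igraph::vcount(h)
  if (is.null(k)) {
    if (ng != nh) {
      stop("graphs have different sizes (", ng, " vs ", nh, "); supply a ",
           "truncation k <= ", min(ng, nh), " to compare them", call. = FALSE)
    }
  } else if (k > min(ng, nh)) {
    stop("`k` must be <= min(vcount(g), vcount(h))", call. = FALSE)
  }
  sg <- graph_spectrum(g, kind, k)$values
  sh <- graph_spectrum(h, kind, k)$values
  lp_norm(sg - sh, p)
}

#' Pooled spectral density
#'
#' Normalized histogram (area 1) of the eigenvalues pooled from a
#' collection of spectra of the same kind, used as a diagnostic of an
#' ensemble's spectral shape (e.g. the semicircular adjacency bulk of an
#' Erdos-Renyi ensemble).
#'
#' @param spectra A list of `graph_spectrum` objects of the same kind, or a
#'   single `graph_spectrum`.
#' @param bins Number of equal-width bins, or a numeric vector of break
#'   points spanning the pooled range.
#' @return A list with `breaks`, `density` (length `length(breaks) - 1`,
#'   integrating to 1), `mids`, and `kind`.
#' @export
spectral_density <- function(spectra, bins = 50) {
  if (inherits(spectra, "graph_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0) stop("`spectra` must be non-empty", call. = FALSE)
  kinds <- vapply(spectra, function(s) s$kind, character(1))
  if (length(unique(kinds)) != 1) {
    stop("all spectra must share the same kind", call. = FALSE)
  }
  values <- unlist(lapply(spectra, function(s) s$values))
  if (length(bins) == 1) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  } else {
    breaks <- as.numeric(bins)
  }
  # left-closed bins: an eigenvalue on an interior break belongs to the
  # bin to its right
  hh <- graphics::hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  list(breaks = hh$breaks, density = hh$density, mids = hh$mids,
       kind = kinds[[1]])
}
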