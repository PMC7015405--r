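# Random-graph ensembles used as study populations: Erdos-Renyi (er),
# two-community stochastic blockmodel (sbm), star-initialized preferential
# attachment (pa), Watts-Strogatz small world (ws), configuration model
# (config), and the 2-d rectangular lattice (lattice). A spec bundles the
# model tag, its parameters, and the connectivity conditioning.

ENSEMBLE_MODELS <- c("er", "sbm", "pa", "ws", "config", "lattice")

#' Ensemble specification
#'
#' Bundles a random-graph model and its parameters into a validated spec
#' consumed by [sample_graph()], [expected_volume()], and
#' [match_volume_er()].
#'
#' Model parameters:
#' \describe{
#'   \item{er}{`n`, `p`: each of the `choose(n, 2)` edges present
#'     independently with probability `p`.}
#'   \item{sbm}{`n`, `p_in`, `q_out`: two balanced communities (sizes
#'     differing by at most one vertex); within-community edges have
#'     probability `p_in`, cross-community edges `q_out`.}
#'   \item{pa}{`n`, `l` with `1 <= l < n`: preferential attachment grown
#'     from a star on `l + 1` vertices; each subsequent vertex attaches to
#'     `l` distinct existing vertices with probability proportional to
#'     current degree, so the edge count is always `l * (n - l)`.}
#'   \item{ws}{`n`, `k` (even, `< n`), `beta`: ring lattice with `k`
#'     nearest neighbors per vertex, each edge rewired with probability
#'     `beta` (edge count `n * k / 2` is conserved).}
#'   \item{config}{`degrees` (a graphical degree sequence) or
#'     `degrees_from` (another spec whose draw's degree sequence is used
#'     per sample): approximately uniform simple graph with those exact
#'     degrees.}
#'   \item{lattice}{`x`, `y`: the deterministic 2-d rectangular grid.}
#' }
#'
#' @param model One of `"er"`, `"sbm"`, `"pa"`, `"ws"`, `"config"`,
#'   `"lattice"`.
#' @param ... Model parameters, as above.
#' @param require_connected Resample until the draw is connected. Defaults
#'   to `TRUE` for er, sbm, and ws (matching the conditioning used in the
#'   population experiments), `FALSE` for pa (connected by construction),
#'   lattice (deterministic), and config.
#' @param max_retries Rejection budget for connectivity conditioning.
#' @return An object of class `ensemble_spec`.
#' @export
#' @examples
#' sp <- ensemble_spec("er", n = 50, p = 0.1)
#' sample_graph(sp, seed = 1)
ensemble_spec <- function(model = ENSEMBLE_MODELS, ...,
                          require_connected = NULL, max_retries = 1000L) {
  model <- match.arg(model)
  params <- list(...)
  pos_int <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= 1 && x == floor(x)
  prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= 0 && x <= 1
  switch(model,
    er = {
      stopifnot(pos_int(params$n), prob(params$p))
    },
    sbm = {
      stopifnot(pos_int(params$n), prob(params$p_in), prob(params$q_out))
    },
    pa = {
      stopifnot(pos_int(params$n), pos_int(params$l))
      if (params$l >= params$n) stop("pa requires 1 <= l < n", call. = FALSE)
    },
    ws = {
      stopifnot(pos_int(params$n), pos_int(params$k), prob(params$beta))
      if (params$k %% 2 != 0 || params$k >= params$n) {
        stop("ws requires an even k < n", call. = FALSE)
      }
    },
    config = {
      if (is.null(params[["degrees"]]) && is.null(params[["degrees_from"]])) {
        stop("config requires `degrees` or `degrees_from`", call. = FALSE)
      }
      if (!is.null(params[["degrees"]])) check_degree_sequence(params[["degrees"]])
      if (!is.null(params[["degrees_from"]]) &&
          !inherits(params[["degrees_from"]], "ensemble_spec")) {
        stop("`degrees_from` must be an ensemble_spec", call. = FALSE)
      }
    },
    lattice = {
      stopifnot(pos_int(params$x), pos_int(params$y))
    }
  )
  if (is.null(require_connected)) {
    require_connected <- model %in% c("er", "sbm", "ws")
  }
  structure(list(model = model, params = params,
                 require_connected = isTRUE(require_connected),
                 max_retries = as.integer(max_retries)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  pstr <- paste(names(x$params), vapply(x$params, function(p) {
    if (inherits(p, "ensemble_spec")) paste0("<", p$model, ">")
    else if (length(p) > 4) paste0("<", length(p), " values>")
    else paste(signif(unlist(p), 6), collapse = ",")
  }, character(1)), sep = "=", collapse = ", ")
  cat(sprintf("<ensemble_spec> %s(%s)%s\n", x$model, pstr,
              if (x$require_connected) " | connected" else ""))
  invisible(x)
}

# Erdos-Gallai feasibility of a degree sequence (plus even-sum check).
check_degree_sequence <- function(degrees) {
  d <- as.integer(degrees)
  if (anyNA(d) || any(d < 0)) {
    stop("degree sequence must be nonnegative integers", call. = FALSE)
  }
  if (sum(d) %% 2 != 0) {
    stop("infeasible degree sequence: odd degree sum", call. = FALSE)
  }
  ds <- sort(d, decreasing = TRUE)
  n <- length(ds)
  lhs <- cumsum(ds)
  for (k in seq_len(n)) {
    rhs <- k * (k - 1) + sum(pmin(ds[-seq_len(k)], k))
    if (lhs[k] > rhs) {
      stop("infeasible degree sequence: Erdos-Gallai condition fails at k = ",
           k, call. = FALSE)
    }
  }
  invisible(d)
}

# star-initialized preferential attachment: |E| = l * (n - l) always
sample_pa_graph <- function(n, l) {
  g_deg <- c(rep(1L, l), l)                 # star on l + 1 vertices
  from <- rep(l + 1L, l)
  to <- seq_len(l)
  deg <- c(g_deg, rep(0L, n - l - 1L))
  for (v in seq(l + 2L, length.out = n - l - 1L)) {
    existing <- seq_len(v - 1L)
    targets <- sample(existing, size = l, prob = deg[existing])
    from <- c(from, rep(v, l))
    to <- c(to, targets)
    deg[targets] <- deg[targets] + 1L
    deg[v] <- l
  }
  igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
}

sample_graph_once <- function(spec) {
  p <- spec$params
  switch(spec$model,
    er = igraph::sample_gnp(p$n, p$p),
    sbm = {
      sizes <- c(ceiling(p$n / 2), floor(p$n / 2))
      pref <- matrix(c(p$p_in, p$q_out, p$q_out, p$p_in), 2, 2)
      igraph::sample_sbm(p$n, pref.matrix = pref, block.sizes = sizes)
    },
    pa = sample_pa_graph(p$n, p$l),
    ws = igraph::sample_smallworld(1, p$n, p$k / 2, p$beta,
                                   loops = FALSE, multiple = FALSE),
    config = {
      degrees <- if (!is.null(p[["degrees"]])) p[["degrees"]] else {
        igraph::degree(sample_graph_once(p[["degrees_from"]]))
      }
      check_degree_sequence(degrees)
      # With connectivity conditioning the Viger-Latapy sampler draws
      # uniformly from exactly the conditioned ensemble (connected simple
      # graphs with the given degrees); otherwise a heuristic stub-matching
      # sampler targets simple graphs with the exact degree sequence.
      method <- if (spec$require_connected && all(degrees > 0)) "vl"
                else "fast.heur.simple"
      igraph::sample_degseq(as.integer(degrees), method = method)
    },
    lattice = igraph::make_lattice(c(p$x, p$y), periodic = FALSE)
  )
}

#' Sample a graph from an ensemble
#'
#' Draws one graph from the spec's generative model, optionally rejecting
#' disconnected draws (connectivity conditioning, i.e. sampling from the
#' model's distribution conditioned on connectedness). Deterministic given
#' `(spec, seed)`: the same pair always yields the same edge set.
#'
#' @param spec An [ensemble_spec()].
#' @param seed Optional integer seed; when supplied, sampling runs in a
#'   local RNG scope (the caller's random state is untouched).
#' @return An undirected simple igraph object.
#' @export
sample_graph <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  draw <- function() {
    if (!spec$require_connected) return(check_graph(sample_graph_once(spec)))
    for (trial in seq_len(spec$max_retries)) {
      g <- sample_graph_once(spec)
      if (igraph::is_connected(g)) return(check_graph(g))
    }
    stop(sprintf(
      "no connected draw from %s in %d attempts (empirical rejection rate 1)",
      spec$model, spec$max_retries), call. = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Expected volume of an ensemble
#'
#' The expected number of edges (for these unweighted models, the expected
#' volume) under the spec's generative model, before any connectivity
#' conditioning.
#'
#' @inheritParams sample_graph
#' @return A nonnegative number.
#' @export
expected_volume <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  p <- spec$params
  switch(spec$model,
    er = p$p * choose(p$n, 2),
    sbm = {
      n1 <- ceiling(p$n / 2); n2 <- floor(p$n / 2)
      p$p_in * (choose(n1, 2) + choose(n2, 2)) + p$q_out * n1 * n2
    },
    pa = p$l * (p$n - p$l),
    ws = p$n * p$k / 2,
    config = {
      if (is.null(p[["degrees"]])) {
        expected_volume(p[["degrees_from"]])
      } else {
        sum(p[["degrees"]]) / 2
      }
    },
    lattice = p$x * (p$y - 1) + p$y * (p$x - 1)
  )
}

#' Volume-matched Erdos-Renyi edge probability
#'
#' The edge probability `p` for which an Erdos-Renyi graph on the same
#' number of vertices has the same expected volume as the given ensemble:
#' `p = E[volume] / choose(n, 2)`. Used to build "structureless" null
#' models that neutralize trivial density differences, e.g.
#' `p(l) = l (n - l) / choose(n, 2)` for preferential attachment.
#'
#' @inheritParams sample_graph
#' @return A probability in `(0, 1)`.
#' @export
#' @examples
#' match_volume_er(ensemble_spec("ws", n = 1000, k = 20, beta = 0.1))
#' # 0.020020...
match_volume_er <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (!spec$model %in% c("pa", "ws", "sbm")) {
    stop("volume matching is defined for pa, ws, and sbm specs", call. = FALSE)
  }
  n <- spec$params$n
  expected_volume(spec) / choose(n, 2)
}
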