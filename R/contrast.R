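# The evaluation protocol. For a null population G0 and an alternative
# population G1, D0 collects distances d(G0, G0') between independent null
# draws and D1 distances d(G0, G1) across populations; the studentized
# contrast (D1 - mean(D0)) / sd(D0) measures separation in units of the
# null population's own variability.

DISTANCE_NAMES <- c("edit", "resistance", "deltacon", "netsimile",
                    "spectral_adjacency", "spectral_laplacian",
                    "spectral_normalized_laplacian")

#' Named distance functions
#'
#' Resolves a distance name plus parameters to a `function(g, h)`, the form
#' consumed by [population_contrast()], [temporal_differences()], and
#' [run_experiment()]. Recognized names: `"edit"`, `"resistance"` (params:
#' `renormalized`), `"deltacon"` (params: `epsilon`, `variant`),
#' `"netsimile"`, and `"spectral_adjacency"`, `"spectral_laplacian"`,
#' `"spectral_normalized_laplacian"` (params: `k`, `p`).
#'
#' @param name A distance name, or already a `function(g, h)` (returned
#'   unchanged).
#' @param params Named list of parameters for the distance.
#' @return A function of two graphs returning a nonnegative number.
#' @export
distance_function <- function(name, params = list()) {
  if (is.function(name)) return(name)
  name <- match.arg(name, DISTANCE_NAMES)
  stopifnot(is.list(params))
  pick <- function(key, default) {
    if (!is.null(params[[key]])) params[[key]] else default
  }
  switch(name,
    edit = function(g, h) edit_distance(g, h),
    resistance = {
      renorm <- isTRUE(pick("renormalized", FALSE))
      function(g, h) resistance_distance(g, h, renormalized = renorm)
    },
    deltacon = {
      eps <- pick("epsilon", NULL)
      variant <- pick("variant", "matusita")
      function(g, h) deltacon(g, h, epsilon = eps, variant = variant)
    },
    netsimile = function(g, h) netsimile_distance(g, h),
    {
      kind <- sub("^spectral_", "", name)
      k <- pick("k", NULL)
      p <- pick("p", 2)
      function(g, h) spectral_distance(g, h, kind = kind, k = k, p = p)
    }
  )
}

#' Contrast summary of two distance samples
#'
#' Builds the studentized contrast from samples of D0 (within-null
#' distances) and D1 (null-vs-alternative distances):
#' `contrast = (D1 - mean(D0)) / sd(D0)`, with the Bessel-corrected sample
#' standard deviation. The summary records the 5th, 25th, 50th, 75th, and
#' 95th percentiles of the contrast samples (the whisker/box/median
#' convention used to report the experiments).
#'
#' @param d0_samples,d1_samples Numeric vectors of distances.
#' @return An object of class `contrast_summary`: a list with
#'   `d0_samples`, `d1_samples`, `mu0`, `sigma0`, `contrast_samples`, and
#'   `quantiles`.
#' @export
#' @examples
#' contrast_summary(c(1, 2, 3), 4)$contrast_samples  # 2
contrast_summary <- function(d0_samples, d1_samples) {
  d0 <- as.numeric(d0_samples)
  d1 <- as.numeric(d1_samples)
  if (length(d0) < 2) stop("need at least 2 null distances", call. = FALSE)
  mu0 <- mean(d0)
  sigma0 <- stats::sd(d0)
  if (!is.finite(sigma0) || sigma0 <= 0) {
    stop("the null population is degenerate (sd of D0 is 0); the contrast ",
         "is undefined — use a stochastic null model", call. = FALSE)
  }
  contrast <- (d1 - mu0) / sigma0
  structure(list(
    d0_samples = d0, d1_samples = d1, mu0 = mu0, sigma0 = sigma0,
    contrast_samples = contrast,
    quantiles = stats::quantile(contrast, c(0.05, 0.25, 0.5, 0.75, 0.95))
  ), class = "contrast_summary")
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf(
    "<contrast_summary> %d null / %d alternative samples\n  mu0 = %.4g, sigma0 = %.4g\n",
    length(x$d0_samples), length(x$d1_samples), x$mu0, x$sigma0))
  print(signif(x$quantiles, 4))
  invisible(x)
}

# Shared draw plan so that the paired spectral k-sweep reproduces
# population_contrast bit-for-bit under the same seed: per-draw seeds are
# spawned from the experiment seed, then each of the n_samples rows draws
# (g0a, g0b) for D0 and (g0c, g1) for D1.
draw_population_graphs <- function(null_spec, alt_spec, n_samples, seed) {
  draw_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 4L * n_samples),
           nrow = n_samples, ncol = 4L)
  })
  list(
    g0a = lapply(seq_len(n_samples), function(i) sample_graph(null_spec, draw_seeds[i, 1])),
    g0b = lapply(seq_len(n_samples), function(i) sample_graph(null_spec, draw_seeds[i, 2])),
    g0c = lapply(seq_len(n_samples), function(i) sample_graph(null_spec, draw_seeds[i, 3])),
    g1  = lapply(seq_len(n_samples), function(i) sample_graph(alt_spec,  draw_seeds[i, 4]))
  )
}

#' Distance contrast between two graph populations
#'
#' Draws `n_samples` independent pairs from the null ensemble to sample D0,
#' and `n_samples` independent null/alternative pairs to sample D1, then
#' studentizes D1 by the mean and standard deviation of D0 (see
#' [contrast_summary()]). A contrast distribution well separated from 0
#' means the distance tells the two populations apart relative to the
#' null's internal variability; the contrast is invariant under any global
#' rescaling of the distance.
#'
#' @param null_spec,alt_spec [ensemble_spec()] objects for the null and
#'   alternative populations.
#' @param distance A distance name or `function(g, h)`; see
#'   [distance_function()].
#' @param n_samples Number of samples of each of D0 and D1 (at least 3).
#' @param seed Integer experiment seed; all graph draws derive from it.
#' @param params Optional parameter list for a named distance.
#' @return A [contrast_summary()].
#' @export
population_contrast <- function(null_spec, alt_spec, distance,
                                n_samples = 20, seed = 1, params = list()) {
  stopifnot(inherits(null_spec, "ensemble_spec"),
            inherits(alt_spec, "ensemble_spec"))
  if (n_samples < 3) stop("`n_samples` must be at least 3", call. = FALSE)
  dfun <- distance_function(distance, params)
  gs <- draw_population_graphs(null_spec, alt_spec, n_samples, seed)
  d0 <- mapply(dfun, gs$g0a, gs$g0b)
  d1 <- mapply(dfun, gs$g0c, gs$g1)
  contrast_summary(d0, d1)
}

#' Spectral contrast as a function of truncation order
#'
#' Recomputes the spectral-distance population contrast for each truncation
#' `k` in `k_values`, reusing one shared set of graph draws across all `k`
#' (a paired design, so differences across `k` reflect the truncation, not
#' sampling noise). With `k = n` the result equals the full-spectrum
#' [population_contrast()] under the same seed exactly.
#'
#' @inheritParams population_contrast
#' @param kind Matrix representation for the spectral distance.
#' @param k_values Integer vector of truncation orders.
#' @param p Norm order, default 2.
#' @return A named list of [contrast_summary()] objects, one per `k`.
#' @export
spectral_k_sweep <- function(null_spec, alt_spec, kind = SPECTRUM_KINDS,
                             k_values, p = 2, n_samples = 20, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(null_spec, "ensemble_spec"),
            inherits(alt_spec, "ensemble_spec"))
  k_values <- as.integer(k_values)
  gs <- draw_population_graphs(null_spec, alt_spec, n_samples, seed)
  spec_of <- function(g) graph_spectrum(g, kind)$values
  s <- lapply(gs, function(glist) lapply(glist, spec_of))
  n_min <- min(vapply(unlist(s, recursive = FALSE), length, integer(1)))
  if (any(k_values < 1 | k_values > n_min)) {
    stop("`k_values` must lie in [1, n] for the generated graphs",
         call. = FALSE)
  }
  out <- lapply(k_values, function(k) {
    idx <- seq_len(k)
    d0 <- mapply(function(a, b) lp_norm(a[idx] - b[idx], p), s$g0a, s$g0b)
    d1 <- mapply(function(a, b) lp_norm(a[idx] - b[idx], p), s$g0c, s$g1)
    contrast_summary(d0, d1)
  })
  names(out) <- as.character(k_values)
  out
}

#' Temporal differences of a dynamic graph
#'
#' For an ordered sequence of graph snapshots, computes the distance
#' between consecutive snapshots, `D(t_i) = d(G_{t_{i-1}}, G_{t_i})`, and
#' the mean-normalized series `D(t) / mean(D)` used to compare different
#' distances on a common scale. Peaks in the normalized series flag
#' candidate change points.
#'
#' @param snapshots A list of at least two igraph objects; distances that
#'   require node correspondence need a common vertex count.
#' @param distance A distance name or `function(g, h)`.
#' @param params Optional parameter list for a named distance.
#' @return A list with `steps` (indices `2:length(snapshots)`),
#'   `differences`, and `normalized` (mean 1 when the mean difference is
#'   positive).
#' @export
temporal_differences <- function(snapshots, distance, params = list()) {
  if (!is.list(snapshots) || length(snapshots) < 2) {
    stop("`snapshots` must be a list of at least two graphs", call. = FALSE)
  }
  dfun <- distance_function(distance, params)
  m <- length(snapshots)
  D <- vapply(seq(2, m), function(i) {
    dfun(snapshots[[i - 1]], snapshots[[i]])
  }, numeric(1))
  Dbar <- mean(D)
  if (Dbar > 0) {
    normalized <- D / Dbar
  } else {
    warning("all temporal differences are zero; normalization skipped",
            call. = FALSE)
    normalized <- D
  }
  list(steps = seq(2, m), differences = D, normalized = normalized)
}

#' Edgewise contrast between two populations of correlation matrices
#'
#' For each region pair `(i, j)`, the difference in mean correlation
#' between population 1 and population 0, in units of the standard
#' deviation of population 0:
#' `(mean1[i,j] - mean0[i,j]) / sd0[i,j]`. This localizes structural
#' differences between two populations of connectomes edge by edge, which
#' whole-graph distances can miss when the signal is confined to a few
#' pairs. The diagonal is 0; pairs with zero null standard deviation are
#' `NA` and counted in the `n_undefined` attribute.
#'
#' @param pop0,pop1 Lists of symmetric correlation matrices of a common
#'   dimension; `pop0` needs at least 2 matrices.
#' @return A symmetric matrix of contrasts with attribute `n_undefined`.
#' @export
edgewise_contrast <- function(pop0, pop1) {
  if (!is.list(pop0) || length(pop0) < 2) {
    stop("`pop0` must be a list of at least 2 matrices", call. = FALSE)
  }
  if (!is.list(pop1) || length(pop1) < 1) {
    stop("`pop1` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- unique(c(vapply(pop0, nrow, integer(1)),
                   vapply(pop1, nrow, integer(1)),
                   vapply(pop0, ncol, integer(1)),
                   vapply(pop1, ncol, integer(1))))
  if (length(dims) != 1) {
    stop("all matrices must have the same square dimension", call. = FALSE)
  }
  arr0 <- simplify2array(pop0)
  arr1 <- simplify2array(pop1)
  mean0 <- apply(arr0, c(1, 2), mean)
  mean1 <- apply(arr1, c(1, 2), mean)
  sd0 <- apply(arr0, c(1, 2), stats::sd)
  out <- (mean1 - mean0) / sd0
  out[sd0 == 0] <- NA_real_
  diag(out) <- 0
  n_undef <- sum(is.na(out))
  if (n_undef > 0) {
    warning(n_undef, " pair(s) have zero null standard deviation; ",
            "contrast undefined there", call. = FALSE)
  }
  attr(out, "n_undefined") <- n_undef
  out
}

#' Synthetic dynamic stochastic blockmodel with a planted change point
#'
#' Generates a sequence of two-community blockmodel snapshots in which the
#' within-community edges are resampled independently at every step
#' (persistent local churn, the noise) while the cross-community edge set
#' is held fixed — the slowly varying community coupling — except at
#' `change_step`, where it is redrawn at `step_factor` times the baseline
#' density and then kept. The planted change is thus the only step at
#' which the coupling between the communities moves, mimicking a dynamic
#' network whose communities persist while their interaction changes at a
#' latent event. Snapshots are conditioned on connectedness so
#' resistance-based distances are defined.
#'
#' @param n Vertex count.
#' @param n_steps Number of snapshots.
#' @param change_step Snapshot index (2..n_steps) at which the
#'   cross-community edge set is redrawn at the stepped-up density.
#' @param p_in Within-community edge probability.
#' @param q_out Baseline cross-community edge probability.
#' @param step_factor Multiplier applied to `q_out` from the change point
#'   onward (default 5).
#' @param seed Integer seed.
#' @return A list of `n_steps` igraph objects with attribute
#'   `change_step`.
#' @export
sample_dynamic_sbm <- function(n = 100, n_steps = 8, change_step = 5,
                               p_in = 0.3, q_out = 0.002, step_factor = 5,
                               seed = 1) {
  stopifnot(change_step >= 2, change_step <= n_steps)
  n1 <- ceiling(n / 2)
  block <- c(rep(1L, n1), rep(2L, n - n1))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  cross <- block[pairs[, 1]] != block[pairs[, 2]]
  withr::with_seed(seed, {
    draw_pairs <- function(idx, prob) idx[stats::runif(length(idx)) < prob]
    cross_idx <- which(cross)
    cross_pre <- draw_pairs(cross_idx, q_out)
    cross_post <- draw_pairs(cross_idx, min(step_factor * q_out, 1))
    within_idx <- which(!cross)
    p_within <- p_in
    build <- function(cross_edges) {
      for (trial in 1:1000) {
        within <- draw_pairs(within_idx, p_within)
        sel <- c(within, cross_edges)
        g <- igraph::make_graph(rbind(pairs[sel, 1], pairs[sel, 2]),
                                n = n, directed = FALSE)
        if (igraph::is_connected(g)) return(g)
      }
      stop("no connected snapshot in 1000 attempts", call. = FALSE)
    }
    snaps <- lapply(seq_len(n_steps), function(t) {
      build(if (t >= change_step) cross_post else cross_pre)
    })
    attr(snaps, "change_step") <- change_step
    snaps
  })
}

#' Synthetic populations of correlation matrices with a planted block
#'
#' Generates two populations of symmetric unit-diagonal correlation
#' matrices: entries are independent Gaussian noise around a zero mean
#' (truncated to `[-1, 1]`), and in population 1 a set of planted region
#' pairs has its mean shifted by `delta`. A stand-in for two populations of
#' functional connectomes with a localized connectivity difference.
#'
#' @param n_regions Matrix dimension (default 116, an atlas-sized matrix).
#' @param n0,n1 Population sizes.
#' @param n_planted Number of planted (upper-triangle) pairs.
#' @param delta Mean shift on planted pairs (default 0.3).
#' @param noise_sd Entry noise standard deviation (default 0.1).
#' @param seed Integer seed.
#' @return A list with `pop0`, `pop1` (lists of matrices), and `planted`
#'   (2-column index matrix of planted pairs).
#' @export
sample_correlation_populations <- function(n_regions = 116, n0 = 20, n1 = 20,
                                           n_planted = 10, delta = 0.3,
                                           noise_sd = 0.1, seed = 1) {
  ut <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  withr::with_seed(seed, {
    planted_idx <- sample.int(nrow(ut), n_planted)
    planted <- ut[planted_idx, , drop = FALSE]
    mu1 <- matrix(0, n_regions, n_regions)
    mu1[planted] <- delta
    mu1 <- mu1 + t(mu1)
    draw <- function(mu) {
      vals <- stats::rnorm(nrow(ut), mean = mu[ut], sd = noise_sd)
      vals <- pmin(pmax(vals, -1), 1)
      m <- matrix(0, n_regions, n_regions)
      m[ut] <- vals
      m <- m + t(m)
      diag(m) <- 1
      m
    }
    list(pop0 = lapply(seq_len(n0), function(i) draw(matrix(0, n_regions, n_regions))),
         pop1 = lapply(seq_len(n1), function(i) draw(mu1)),
         planted = planted)
  })
}
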