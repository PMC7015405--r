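test_that("contrast summary studentizes by the null sample moments", {
  # d0 = {1, 2, 3}: mu0 = 2, Bessel-corrected sd = 1; d1 = {4} -> contrast 2
  cs <- contrast_summary(c(1, 2, 3), 4)
  expect_equal(cs$mu0, 2)
  expect_equal(cs$sigma0, 1)
  expect_equal(cs$contrast_samples, 2)
  expect_error(contrast_summary(c(2, 2, 2), 3), "degenerate")
  expect_error(contrast_summary(2, 3), "at least 2")
})

test_that("the contrast is invariant under global rescaling of the distance", {
  d0 <- c(0.3, 0.5, 0.8, 0.4); d1 <- c(1.1, 0.9, 1.4)
  a <- contrast_summary(d0, d1)
  b <- contrast_summary(7.3 * d0, 7.3 * d1)
  expect_equal(a$contrast_samples, b$contrast_samples, tolerance = 1e-12)
  expect_equal(a$quantiles, b$quantiles, tolerance = 1e-12)
})

test_that("a population compared with itself has contrast centered at zero", {
  er <- ensemble_spec("er", n = 40, p = 0.2)
  cs <- population_contrast(er, er, "edit", n_samples = 100, seed = 11)
  se <- stats::sd(cs$contrast_samples) / sqrt(length(cs$contrast_samples))
  expect_lt(abs(mean(cs$contrast_samples)), 3 * se + 1e-12)
})

test_that("population contrast is reproducible and accepts function distances", {
  er <- ensemble_spec("er", n = 30, p = 0.25)
  ws <- ensemble_spec("ws", n = 30, k = 4, beta = 0.2)
  a <- population_contrast(er, ws, "deltacon", n_samples = 5, seed = 21)
  b <- population_contrast(er, ws, "deltacon", n_samples = 5, seed = 21)
  expect_identical(a$contrast_samples, b$contrast_samples)
  f <- population_contrast(er, ws, function(g, h) deltacon(g, h),
                           n_samples = 5, seed = 21)
  expect_identical(f$contrast_samples, a$contrast_samples)
})

test_that("volume-matched models are invisible to the edit distance", {
  sbm <- ensemble_spec("sbm", n = 120, p_in = 1.9 * 0.1, q_out = 0.1 * 0.1)
  er <- ensemble_spec("er", n = 120, p = match_volume_er(sbm))
  cs <- population_contrast(er, sbm, "edit", n_samples = 20, seed = 31)
  expect_lt(abs(cs$quantiles[["50%"]]), 1)
})

test_that("the k-sweep at full truncation reproduces the unswept contrast exactly", {
  er <- ensemble_spec("er", n = 30, p = 0.25)
  ws <- ensemble_spec("ws", n = 30, k = 4, beta = 0.2)
  sweep <- spectral_k_sweep(er, ws, "adjacency", k_values = c(2, 30),
                            n_samples = 6, seed = 41)
  full <- population_contrast(er, ws, "spectral_adjacency", n_samples = 6,
                              seed = 41)
  expect_identical(sweep[["30"]]$contrast_samples, full$contrast_samples)
  expect_identical(sweep[["30"]]$d0_samples, full$d0_samples)
  expect_error(spectral_k_sweep(er, ws, "adjacency", k_values = 31,
                                n_samples = 4, seed = 1), "k_values")
})

test_that("temporal differences flag identical snapshots with zeros", {
  g <- random_connected_gnp(20, 0.3, seed = 51)
  h <- perturb_edge(g, 1, as.integer(igraph::neighbors(g, 1)[1]), -1)
  ts <- temporal_differences(list(g, g, h), "edit")
  expect_equal(ts$differences[1], 0)
  expect_gt(ts$differences[2], 0)
  expect_equal(mean(ts$normalized), 1)
  expect_warning(temporal_differences(list(g, g), "edit"), "zero")
  expect_error(temporal_differences(list(g), "edit"), "at least two")
})

test_that("the dynamic blockmodel plants its change at the declared step", {
  snaps <- sample_dynamic_sbm(n = 60, n_steps = 6, change_step = 4,
                              q_out = 0.004, seed = 61)
  expect_length(snaps, 6)
  expect_equal(attr(snaps, "change_step"), 4)
  expect_true(all(vapply(snaps, igraph::is_connected, logical(1))))
  # the cross-community edge set is frozen away from the change step
  block <- rep(1:2, each = 30)
  cross_edges <- function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    el[block[el[, 1]] != block[el[, 2]], , drop = FALSE]
  }
  expect_identical(cross_edges(snaps[[1]]), cross_edges(snaps[[3]]))
  expect_identical(cross_edges(snaps[[4]]), cross_edges(snaps[[6]]))
})

test_that("resistance finds the planted change point where edit is unreliable", {
  hits_r <- 0; hits_e <- 0
  n_runs <- 20
  for (r in seq_len(n_runs)) {
    snaps <- sample_dynamic_sbm(seed = 7100 + r)
    cp <- attr(snaps, "change_step")
    ts_r <- temporal_differences(snaps, "resistance")
    ts_e <- temporal_differences(snaps, "edit")
    hits_r <- hits_r + (ts_r$steps[which.max(ts_r$normalized)] == cp)
    hits_e <- hits_e + (ts_e$steps[which.max(ts_e$normalized)] == cp)
  }
  expect_gte(hits_r, 0.9 * n_runs)
  expect_lt(hits_e, 0.9 * n_runs)
})

test_that("edgewise contrast matches hand arithmetic and handles degeneracy", {
  base <- function(v12, v13 = 0, v23 = 0) {
    m <- diag(3); m[1, 2] <- m[2, 1] <- v12; m[1, 3] <- m[3, 1] <- v13
    m[2, 3] <- m[3, 2] <- v23; m
  }
  pop0 <- list(base(0.1), base(0.3))
  pop1 <- list(base(0.5), base(0.5))
  expect_warning(ec <- edgewise_contrast(pop0, pop1), "zero null")
  expect_equal(ec[1, 2], (0.5 - 0.2) / stats::sd(c(0.1, 0.3)),
               tolerance = 1e-10)
  expect_equal(ec[1, 2], 2.1213, tolerance = 1e-4)
  expect_equal(ec, t(ec))
  expect_equal(diag(ec), rep(0, 3))
  expect_true(is.na(ec[2, 3]))  # sd0 = 0 there
  # identical populations: zero contrast everywhere
  pop <- lapply(1:3, function(i) base(0.1 * i, 0.05 * i, 0.02 * i))
  ec0 <- edgewise_contrast(pop, pop)
  expect_equal(max(abs(ec0)), 0)
  expect_equal(attr(ec0, "n_undefined"), 0)
  expect_error(edgewise_contrast(pop0[1], pop1), "at least 2")
})

test_that("a planted correlation block is top-ranked by the edgewise contrast", {
  hits <- 0; n_runs <- 10
  for (r in seq_len(n_runs)) {
    pops <- sample_correlation_populations(n_regions = 60, seed = 8200 + r)
    ec <- edgewise_contrast(pops$pop0, pops$pop1)
    ut <- which(upper.tri(ec), arr.ind = TRUE)
    top <- ut[order(ec[upper.tri(ec)], decreasing = TRUE)[1:10], , drop = FALSE]
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    hits <- hits + all(key(pops$planted) %in% key(top))
  }
  expect_gte(hits, 9)
})

test_that("correlation populations are valid correlation-like matrices", {
  pops <- sample_correlation_populations(n_regions = 30, n0 = 3, n1 = 3,
                                         seed = 91)
  for (m in c(pops$pop0, pops$pop1)) {
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(1, 30))
    expect_true(all(abs(m) <= 1))
  }
  expect_equal(nrow(pops$planted), 10)
})
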