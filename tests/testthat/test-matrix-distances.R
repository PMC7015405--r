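test_that("edit distance counts edge discrepancies twice", {
  expect_equal(edit_distance(K3, P3), 2)
  expect_equal(edit_distance(K3, K3), 0)
  expect_error(edit_distance(K3, igraph::make_ring(4)), "node correspondence")
})

test_that("edit distance equals twice the symmetric difference on random pairs", {
  for (s in 1:15) {
    n <- 6 + s %% 10
    g <- sample_graph(ensemble_spec("er", n = n, p = 0.4,
                                    require_connected = FALSE), seed = 2 * s)
    h <- sample_graph(ensemble_spec("er", n = n, p = 0.4,
                                    require_connected = FALSE), seed = 2 * s + 1)
    symdiff <- length(union(setdiff(edge_key_set(g), edge_key_set(h)),
                            setdiff(edge_key_set(h), edge_key_set(g))))
    expect_equal(edit_distance(g, h), 2 * symdiff)
  }
})

test_that("weighted edit distance sums absolute weight differences", {
  g <- weighted_edge()                       # edge (1,2) weight 2.5
  h <- igraph::make_graph(~ A-B, B-C)        # edges (1,2), (2,3) weight 1
  # ordered pairs: |2.5 - 1| * 2 + |0 - 1| * 2
  expect_equal(edit_distance(g, h), 2 * 1.5 + 2 * 1)
})

test_that("effective resistance follows the circuit laws", {
  R <- resistance_matrix(P3)
  expect_equal(R[1, 2], 1, tolerance = 1e-10)
  expect_equal(R[2, 3], 1, tolerance = 1e-10)
  expect_equal(R[1, 3], 2, tolerance = 1e-10)
  RK <- resistance_matrix(K3)
  expect_equal(RK[upper.tri(RK)], rep(2 / 3, 3), tolerance = 1e-10)
  expect_equal(diag(RK), rep(0, 3))
  # weighted: conductance = weight; series law 1/2.5 on the single edge
  Rw <- resistance_matrix(igraph::induced_subgraph(weighted_edge(), 1:2))
  expect_equal(Rw[1, 2], 1 / 2.5, tolerance = 1e-10)
  expect_error(resistance_matrix(igraph::make_graph(~ a-b, c-d)),
               "renormalized")
})

test_that("on trees resistance equals shortest-path edge counts", {
  trees <- list(asym_tree,
                withr::with_seed(8, igraph::sample_tree(12)),
                withr::with_seed(9, igraph::sample_tree(20)))
  for (tr in trees) {
    expect_equal(resistance_matrix(tr),
                 igraph::distances(tr, weights = NA), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("resistance matrices are vertex metrics on random connected graphs", {
  for (s in 1:20) {
    g <- random_connected_gnp(6 + s, 0.35, seed = 500 + s)
    R <- resistance_matrix(g)
    n <- nrow(R)
    expect_true(all(R >= 0))
    expect_equal(R, t(R), tolerance = 1e-10)
    # triangle inequality over all vertex triples
    ok <- TRUE
    for (u in 1:n) {
      viol <- R[u, ] + rep(R[u, ], each = n) - as.vector(R) < -1e-8
      ok <- ok && !any(viol)
    }
    expect_true(ok)
  }
})

test_that("resistance distance reproduces the toy value and needs correspondence", {
  expect_equal(resistance_distance(P3, K3), 4, tolerance = 1e-9)
  expect_equal(resistance_distance(K3, K3), 0, tolerance = 1e-12)
  # node-correspondence dependence: relabelling a tree so its hub moves to
  # the star's center changes the distance to the fixed star
  perm <- c(2, 1, 3, 4, 5)
  other <- igraph::make_graph(~ a-b, a-c, a-d, a-e)  # star
  d1 <- resistance_distance(asym_tree, other)
  d2 <- resistance_distance(permute_graph(asym_tree, perm), other)
  expect_gt(abs(d1 - d2), 1e-6)
  expect_error(resistance_distance(P3, igraph::make_ring(4)),
               "node correspondence")
})

test_that("renormalized resistance is bounded, limit-consistent, and monotone", {
  # connected pair with R = 1 maps to 1/2
  rho <- renormalized_resistance_matrix(P3)
  expect_equal(rho[1, 2], 1 / 2, tolerance = 1e-10)
  expect_equal(rho[1, 3], 2 / 3, tolerance = 1e-10)
  # disconnected pairs sit at the R -> Inf limit
  g <- igraph::make_graph(~ a-b, c-d)
  rho2 <- renormalized_resistance_matrix(g)
  expect_equal(rho2[1, 3], 1)
  expect_equal(rho2[2, 4], 1)
  expect_equal(rho2[1, 2], 1 / 2, tolerance = 1e-10)
  expect_true(all(rho2 >= 0 & rho2 <= 1))
  # within one component the transform preserves the affinity ordering
  gc <- random_connected_gnp(12, 0.3, seed = 31)
  R <- resistance_matrix(gc)
  rho3 <- renormalized_resistance_matrix(gc)
  ut <- upper.tri(R)
  expect_equal(rho3[ut], R[ut] / (1 + R[ut]), tolerance = 1e-12)
  expect_gte(stats::cor(R[ut], rho3[ut], method = "spearman"), 0.999)
  # renormalized flag makes the distance accept disconnected inputs
  expect_silent(resistance_distance(g, permute_graph(g, c(2, 1, 3, 4)),
                                    renormalized = TRUE))
})

test_that("fast belief propagation matrix matches its definition and series", {
  expect_equal(fbp_matrix(P3, 0), diag(3))
  S <- fbp_matrix(igraph::make_graph(~ a-b), 0.1)
  expect_equal(S, solve(matrix(c(1.01, -0.1, -0.1, 1.01), 2, 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(S[1, 1], 0.99990, tolerance = 1e-4)
  expect_equal(S[1, 2], 0.09900, tolerance = 1e-4)
  # series: || S - (I + eps A + eps^2 (A^2 - D)) ||_max = O(eps^3)
  for (s in 1:5) {
    g <- random_connected_gnp(12, 0.35, seed = 600 + s)
    A <- matrix_representation(g, "adjacency")
    D <- diag(graph_degrees(g))
    err <- function(eps) {
      max(abs(fbp_matrix(g, eps) - (diag(nrow(A)) + eps * A + eps^2 * (A %*% A - D))))
    }
    ratio <- err(1e-2) / err(1e-3)
    expect_gt(ratio, 10^2.5)   # cubic scaling: factor ~1000 per decade
    expect_lt(ratio, 10^3.5)
  }
})

test_that("DeltaCon vanishes on identity, is symmetric, and tracks perturbation size", {
  g <- random_connected_gnp(30, 0.2, seed = 41)
  expect_equal(deltacon(g, g), 0, tolerance = 1e-10)
  h <- random_connected_gnp(30, 0.2, seed = 42)
  expect_equal(deltacon(g, h), deltacon(h, g), tolerance = 1e-12)
  expect_error(deltacon(g, K3), "node correspondence")
  # adding two disjoint edges moves the graph at least as far as one of them
  wins <- 0
  for (s in 1:100) {
    g0 <- sample_graph(ensemble_spec("er", n = 50, p = 0.1), seed = 700 + s)
    miss <- which(matrix_representation(g0, "adjacency") == 0 &
                    upper.tri(diag(50)), arr.ind = TRUE)
    pick <- withr::with_seed(800 + s, {
      repeat {
        rows <- sample(nrow(miss), 2)
        if (length(unique(as.vector(miss[rows, ]))) == 4) break
      }
      rows
    })
    e1 <- miss[pick[1], ]; e2 <- miss[pick[2], ]
    g1 <- perturb_edge(g0, e1[1], e1[2], 1)
    g2 <- perturb_edge(g1, e2[1], e2[2], 1)
    d1 <- deltacon(g0, g1); d2 <- deltacon(g0, g2)
    expect_gt(d1, 0)
    wins <- wins + (d2 >= d1)
  }
  expect_gte(wins, 90)
})

test_that("the printed DeltaCon variant differs from Matusita but agrees at zero", {
  g <- random_connected_gnp(20, 0.25, seed = 51)
  h <- random_connected_gnp(20, 0.25, seed = 52)
  expect_equal(deltacon(g, g, variant = "printed"), 0, tolerance = 1e-12)
  expect_gt(deltacon(g, h, variant = "printed"), 0)
})

test_that("matrix distances vanish continuously as a perturbation shrinks", {
  g <- random_connected_gnp(15, 0.35, seed = 61)
  nb <- as.integer(igraph::neighbors(g, 1)[1])
  d_res <- vapply(c(1e-3, 1e-6), function(dw) {
    resistance_distance(g, perturb_edge(g, 1, nb, dw))
  }, numeric(1))
  d_dc <- vapply(c(1e-3, 1e-6), function(dw) {
    deltacon(g, perturb_edge(g, 1, nb, dw))
  }, numeric(1))
  expect_lt(d_res[2], d_res[1])
  expect_lt(d_res[2], 1e-3)
  expect_lt(d_dc[2], d_dc[1])
  expect_lt(d_dc[2], 1e-3)
})

test_that("single-edge closed form matches direct recomputation", {
  expect_equal(rp_single_edge(K3, 1, 2, 0), 0)
  # removing one K3 edge: closed form vs direct resistance recomputation
  direct <- resistance_distance(K3, perturb_edge(K3, 1, 2, -1))
  expect_equal(rp_single_edge(K3, 1, 2, -1), direct, tolerance = 1e-9)
  # random graphs, random perturbations (including edge additions/removals)
  for (s in 1:50) {
    n <- 8 + s %% 33
    g <- random_connected_gnp(n, 0.3, seed = 900 + s)
    A <- matrix_representation(g, "adjacency")
    pair <- withr::with_seed(950 + s, sample(n, 2))
    i <- pair[1]; j <- pair[2]
    w_cur <- A[i, j]
    dw <- withr::with_seed(990 + s, stats::runif(1, min = -w_cur, max = 1))
    gp <- perturb_edge(g, i, j, dw)
    if (!igraph::is_connected(gp)) next  # removed a bridge: undefined
    direct <- resistance_distance(g, gp)
    closed <- rp_single_edge(g, i, j, dw)
    if (direct > 1e-12) {
      expect_lt(abs(closed - direct) / direct, 1e-6)
    } else {
      expect_lt(closed, 1e-9)
    }
  }
})

test_that("closed form rejects perturbations that disconnect the graph", {
  expect_error(rp_single_edge(P3, 1, 2, -1), "disconnect")
  expect_error(rp_single_edge(igraph::make_graph(~ a-b, c-d), 1, 3, 1),
               "connected")
})

test_that("all matrix distances are symmetric and vanish on identical inputs", {
  g <- random_connected_gnp(15, 0.3, seed = 71)
  h <- random_connected_gnp(15, 0.3, seed = 72)
  for (d in list(edit_distance, resistance_distance, deltacon,
                 netsimile_distance)) {
    expect_lt(d(g, g), 1e-10)
    expect_equal(d(g, h), d(h, g), tolerance = 1e-12)
  }
})
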