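# Graph metrics: closed-form cases, brute-force oracle equivalence,
# null-model normalization, curve integration.

k_n <- function(n) { a <- matrix(1L, n, n); diag(a) <- 0L; a }
path_n <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}
star_n <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

test_that("closed-form values on canonical small graphs", {
  expect_equal(clustering_coefficient(k_n(3)), 1)
  expect_equal(clustering_coefficient(star_n(4)), 0)
  # K4 minus edge (3,4), by enumeration: nodes 1,2 see 2 of 3 neighbor
  # pairs linked (2/3); nodes 3,4 see their single pair linked (1)
  k4e <- k_n(4); k4e[3, 4] <- k4e[4, 3] <- 0L
  expect_equal(clustering_coefficient(k4e), mean(c(2 / 3, 2 / 3, 1, 1)))
  expect_equal(clustering_coefficient(k4e), oracle_cp(k4e))
  expect_equal(characteristic_path_length(k_n(3)), 1)
  expect_equal(characteristic_path_length(path_n(3)), 4 / 3)
  two_edges <- matrix(0L, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1L
  expect_equal(characteristic_path_length(two_edges), 1)  # connected pairs only
  expect_error(characteristic_path_length(matrix(0L, 3, 3)), "no edges")
  expect_equal(global_efficiency(k_n(6)), 1)
  expect_equal(global_efficiency(path_n(3)), 5 / 6)
  expect_equal(global_efficiency(matrix(0L, 4, 4)), 0)
  expect_equal(local_efficiency(k_n(4)), 1)
  expect_equal(local_efficiency(star_n(5)), 0)
  # K4 minus one edge, by enumeration: nodes (5/6, 5/6, 1, 1)
  expect_equal(local_efficiency(k4e), oracle_eloc(k4e))
  expect_equal(local_efficiency(k4e), mean(c(5 / 6, 5 / 6, 1, 1)))
  expect_equal(nodal_efficiency(star_n(6), 1), 1)
  expect_equal(nodal_efficiency(path_n(3), 1), 3 / 4)
  iso <- matrix(0L, 3, 3); iso[1, 2] <- iso[2, 1] <- 1L
  expect_equal(nodal_efficiency(iso, 3), 0)
})

test_that("all metrics match brute-force enumeration on random graphs", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    a <- random_graph(n, runif(1, 0.15, 0.8))
    expect_equal(clustering_coefficient(a), oracle_cp(a), tolerance = 1e-12)
    expect_equal(global_efficiency(a), oracle_eglob(a), tolerance = 1e-12)
    expect_equal(local_efficiency(a), oracle_eloc(a), tolerance = 1e-12)
    expect_equal(nodal_efficiency(a), oracle_enod(a), tolerance = 1e-12)
    if (sum(a) > 0)
      expect_equal(characteristic_path_length(a), oracle_lp(a),
                   tolerance = 1e-12)
    m <- fnirsnet:::graph_metrics_cpp(fnirsnet:::as_binary_adjacency(a))
    expect_equal(m$cp, oracle_cp(a), tolerance = 1e-12)
    expect_equal(m$eloc, oracle_eloc(a), tolerance = 1e-12)
  }
})

test_that("metric definitions coincide with the igraph conventions", {
  set.seed(13)
  for (i in 1:15) {
    a <- random_graph(10, 0.4)
    if (sum(a) == 0) next
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(clustering_coefficient(a),
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
                 tolerance = 1e-12)
    expect_equal(characteristic_path_length(a),
                 igraph::mean_distance(g, unconnected = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("degree-preserving nulls normalize sigma to ~1 on random graphs", {
  set.seed(14)
  sig <- replicate(15, {
    a <- random_graph(27, 0.3)
    small_worldness(a, n_random = 40)
  })
  expect_gt(mean(sig), 0.9)
  expect_lt(mean(sig), 1.1)
})

test_that("a small-world lattice rewiring has sigma above 1", {
  set.seed(15)
  g <- igraph::sample_smallworld(1, 27, 2, 0.1)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  a <- 1L * (a > 0); diag(a) <- 0L
  expect_gt(small_worldness(a, n_random = 50), 1)
})

test_that("rewired null networks preserve every degree exactly", {
  set.seed(16)
  a <- random_graph(20, 0.3)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  for (i in 1:5) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 200))
    expect_equal(igraph::degree(gr), igraph::degree(g))
  }
})

test_that("curve integration follows the trapezoid rule", {
  grid <- seq(0.13, 0.40, by = 0.01)
  expect_equal(metric_auc(rep(2, length(grid)), grid), 2 * 0.27,
               tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = length(grid))
  expect_equal(metric_auc(ramp, grid), 0.5 * 0.27, tolerance = 1e-12)
  expect_equal(metric_auc(c(1, 1, 4), c(0, 1, 2), rule = "rectangle"), 2)
  expect_error(metric_auc(1, 0.13), "two grid points")
  expect_error(metric_auc(c(1, 2), c(0.2, 0.1)), "increasing")
  expect_error(metric_auc(c(1, 2, 3), c(0.1, 0.2)), "length")
})

test_that("efficiency grows with sparsity and bounds 1/Lp on the ensemble", {
  set.seed(17)
  z <- matrix(rnorm(27^2), 27); z <- (z + t(z)) / 2; diag(z) <- 0
  ens <- binarize_by_sparsity(z)
  mc <- network_metric_curves(ens, include_sigma = FALSE)
  expect_true(all(diff(mc$eglob) >= -1e-12))   # adding edges never hurts
  for (g in seq_along(ens$sparsity)) {
    a <- ens$adjacency[, , g]
    d <- fnirsnet:::shortest_path_lengths(a)
    if (all(is.finite(d)))
      expect_gte(mc$eglob[g], 1 / mc$lp[g] - 1e-12)  # Jensen
  }
  # AUCs recompute from the stored curves
  expect_equal(mc$auc$eglob, metric_auc(mc$eglob, mc$sparsity))
  expect_equal(mc$auc$enod[3], metric_auc(mc$enod[3, ], mc$sparsity))
})

test_that("sigma is seeded and reproducible", {
  set.seed(18)
  a <- random_graph(27, 0.25)
  set.seed(100); s1 <- small_worldness(a, n_random = 20)
  set.seed(100); s2 <- small_worldness(a, n_random = 20)
  expect_identical(s1, s2)
})
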