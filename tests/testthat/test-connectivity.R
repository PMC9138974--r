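test_that("connectivity_matrix thresholds correlations by significance", {
  set.seed(3)
  x <- rbinom(500, 1, 0.3)
  st <- rbind(x, x, rbinom(500, 1, 0.3), rep(1L, 500))
  A <- connectivity_matrix(binned_matrix(st, 0.03), alpha = 0.05)
  # duplicated neuron: perfect, significant correlation
  expect_equal(A$weights[1, 2], 1)
  # constant neuron: undefined correlation treated as non-significant
  expect_true(all(A$weights[4, ] == 0))
  # symmetry and zero diagonal
  expect_equal(A$weights, t(A$weights))
  expect_true(all(diag(A$weights) == 0))
  expect_error(connectivity_matrix(coin_binned(1, 100)), "2 neurons")
})

test_that("false-edge density under independence is near alpha", {
  b <- coin_binned(20, 1e4, p = 0.2, seed = 41)
  A <- connectivity_matrix(b, alpha = 0.05)
  off <- A$weights[upper.tri(A$weights)]
  density <- mean(off > 0)
  # binomial 3-sigma band around alpha over 190 pair tests
  tol <- 3 * sqrt(0.05 * 0.95 / length(off))
  expect_lt(abs(density - 0.05), tol + 1e-12)
})

test_that("modularity_score matches hand-computed and degenerate values", {
  W <- two_triangles()
  # two disconnected unit triangles, planted 2-community labeling:
  # M = (12 - 6)/12 = 1/2 by direct summation
  expect_equal(modularity_score(W, c(0, 0, 0, 1, 1, 1)), 0.5)
  # everything in one community: exactly zero for any graph
  expect_equal(modularity_score(W, rep(0, 6)), 0)
  set.seed(2)
  R <- matrix(runif(36), 6); R <- R + t(R); diag(R) <- 0
  expect_equal(modularity_score(R, rep(1, 6)), 0, tolerance = 1e-12)
  # all singletons with no within edges: only null-model terms remain
  expect_equal(modularity_score(W, 0:5), -1 / 6)
  expect_error(modularity_score(matrix(0, 3, 3), c(0, 1, 2)), "empty graph")
  # agrees with a direct ordered-pair transcription on random graphs
  for (seed in 1:3) {
    set.seed(seed)
    comm <- sample(0:2, 6, replace = TRUE)
    expect_equal(modularity_score(R, comm), naive_modularity(R, comm),
                 tolerance = 1e-12)
  }
})

test_that("louvain recovers components and degrades gracefully", {
  W <- two_triangles()
  ca <- louvain(W, seed = 1)
  expect_equal(ca$modularity, 0.5)
  expect_equal(ca$community_of[1:3], rep(ca$community_of[1], 3))
  expect_equal(ca$community_of[4:6], rep(ca$community_of[4], 3))
  expect_false(ca$community_of[1] == ca$community_of[4])
  # community ids contiguous from 0
  expect_setequal(unique(ca$community_of), 0:1)

  # fully connected uniform graph: no structure to find
  K <- matrix(1, 8, 8); diag(K) <- 0
  ck <- louvain(K, seed = 2)
  expect_gte(ck$modularity, 0)
  expect_equal(length(unique(ck$community_of)), 1)
  expect_error(louvain(matrix(0, 4, 4)), "empty graph")
})

test_that("louvain modularity bookkeeping and monotonicity hold on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    W <- matrix(rbinom(n * n, 1, 0.3) * runif(n * n), n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    if (sum(W) == 0) next
    ca <- louvain(W, seed = seed)
    # reported modularity equals recomputation on the returned assignment
    expect_equal(ca$modularity, modularity_score(W, ca$community_of),
                 tolerance = 1e-9)
    # never worse than the all-singletons start
    expect_gte(ca$modularity, modularity_score(W, seq_len(n) - 1) - 1e-12)
  }
})

test_that("louvain is near the exhaustive modularity optimum for small graphs", {
  for (seed in c(1, 7)) {
    set.seed(seed)
    n <- 7
    W <- matrix(rbinom(n * n, 1, 0.4) * runif(n * n, 0.2, 1), n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    best <- max(vapply(set_partitions(n), function(p) {
      comm <- integer(n)
      for (k in seq_along(p)) comm[p[[k]]] <- k
      modularity_score(W, comm)
    }, numeric(1)))
    got <- louvain(W, seed = 0)$modularity
    if (best > 0) expect_gte(got, 0.95 * best)
  }
})

test_that("louvain agrees with the igraph reference on a clustered graph", {
  set.seed(12)
  n <- 12
  memb <- rep(1:3, each = 4)
  P <- ifelse(outer(memb, memb, "=="), 0.9, 0.05)
  W <- matrix(rbinom(n * n, 1, P), n) * 1
  W <- pmax(W, t(W)); diag(W) <- 0
  ours <- louvain(W, seed = 0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::cluster_louvain(g)
  expect_equal(ours$modularity, igraph::modularity(g, igraph::membership(ref)),
               tolerance = 0.05)
})

test_that("louvain_partition maps communities to partitions with fallbacks", {
  # two groups of mutually duplicated trains, uncorrelated between groups
  set.seed(8)
  x <- rbinom(2000, 1, 0.3); y <- rbinom(2000, 1, 0.3)
  st <- rbind(x, x, x, y, y, y)
  p <- louvain_partition(binned_matrix(st, 0.03), alpha = 0.05, seed = 0)
  expect_equal(p$r, 2)
  expect_true(identical(sort(p$subsets[[1]]), 1:3) ||
              identical(sort(p$subsets[[1]]), 4:6))

  # independent trains: empty graph => atomic fallback with warning
  b0 <- coin_binned(5, 200, p = 0.3, seed = 101)
  A0 <- connectivity_matrix(b0, alpha = 1e-6)
  if (sum(A0$weights) == 0) {
    expect_warning(p0 <- louvain_partition(b0, alpha = 1e-6), "atomic")
    expect_equal(p0$r, 5)
  }
})
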