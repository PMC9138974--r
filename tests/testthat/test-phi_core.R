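test_that("estimate_gaussian_model recovers known second-order structure", {
  # constant-zero neuron: zero row/column, flagged degenerate
  st <- rbind(rep(0L, 200), rbinom(200, 1, 0.5))
  m <- estimate_gaussian_model(binned_matrix(st, 0.03), 1)
  expect_equal(unname(m$cov0[1, ]), c(0, 0))
  expect_equal(m$degenerate, "n1")
  expect_equal(m$n_samples, 199)

  # fair-coin neuron: variance ~ 1/4, lagged autocovariance ~ 0
  b <- coin_binned(1, 1e5, seed = 7)
  m1 <- estimate_gaussian_model(b, 1)
  expect_lt(abs(m1$cov0[1, 1] - 0.25), 0.01)
  expect_lt(abs(m1$covlag[1, 1]), 0.01)

  # copy-pair: neuron 2 = neuron 1 shifted by the lag => covlag[1,2] equals
  # the variance of neuron 1, exactly
  set.seed(11)
  lag <- 3
  x <- rbinom(500, 1, 0.4)
  st2 <- rbind(x, c(rep(0L, lag), x[1:(500 - lag)]))
  m2 <- estimate_gaussian_model(binned_matrix(st2, 0.03), lag)
  expect_equal(m2$covlag[1, 2], m2$cov0[1, 1], tolerance = 1e-12)
})

test_that("residual_covariance implements the least-squares residual formula", {
  # nothing predictable: covlag = 0 => residual covariance equals cov0
  m <- gaussian_model(diag(c(2, 3)), matrix(0, 2, 2), 1)
  expect_equal(unname(residual_covariance(m, 1:2)), diag(c(2, 3)))

  # perfect self-copy channel: residual is zero
  m2 <- gaussian_model(matrix(1), matrix(1), 1)
  expect_equal(residual_covariance(m2, 1), matrix(0, 1, 1, dimnames = list("n1", "n1")),
               ignore_attr = TRUE)

  # hand-derived 2-node case: cov0 = I, cross-only lag coupling c
  m3 <- gaussian_model(diag(2), matrix(c(0, 0, 0.5, 0), 2, 2), 1)
  expect_equal(unname(residual_covariance(m3, 1:2)),
               diag(c(1, 1 - 0.25)), tolerance = 1e-12)

  # singular block raises the rank-deficiency condition class
  m4 <- gaussian_model(matrix(c(1, 1, 1, 1), 2), matrix(0, 2, 2), 1)
  expect_error(residual_covariance(m4, 1:2),
               class = "phispike_rank_deficient")
})

test_that("phi_ar matches the closed-form two-node value and conventions", {
  m <- gaussian_model(diag(2), matrix(c(0, 0, 0.5, 0), 2, 2), 1)
  p <- phi_partition(list(1, 2))
  r <- phi_ar(m, p)
  # whole system: det Sigma(E) = 1 - c^2 = 0.75; parts predict nothing
  expect_equal(r$phi_raw, 0.5 * log(1 / 0.75), tolerance = 1e-12)
  expect_equal(r$normalization, 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  expect_equal(r$phi, r$phi_raw / r$normalization, tolerance = 1e-12)

  # single-subset partition: phi = 0 by definition
  r1 <- phi_ar(m, phi_partition(list(1:2)))
  expect_equal(r1$phi, 0)

  # unnormalized flag
  expect_equal(phi_ar(m, p, normalize = FALSE)$phi, r$phi_raw)
})

test_that("block-diagonal models give phi_raw = 0 to machine precision", {
  bdiag2 <- function(a, b) {
    out <- matrix(0, nrow(a) + nrow(b), ncol(a) + ncol(b))
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out[nrow(a) + seq_len(nrow(b)), ncol(a) + seq_len(ncol(b))] <- b
    out
  }
  for (seed in 1:3) {
    m1 <- random_var_model(3, seed)
    m2 <- random_var_model(2, seed + 100)
    cov0 <- bdiag2(m1$cov0, m2$cov0)
    covlag <- bdiag2(m1$covlag, m2$covlag)
    g <- gaussian_model(cov0, covlag, 1)
    r <- phi_ar(g, phi_partition(list(1:3, 4:5)))
    expect_lt(abs(r$phi_raw), 1e-10)
  }
})

test_that("residual covariance is PSD and cannot increase generalized variance", {
  for (seed in 1:5) {
    v <- random_var_model(4, seed)
    for (s in list(1:4, c(1L, 3L), 2L)) {
      E <- residual_covariance(v$model, s)
      expect_gte(min(eigen(E, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
      expect_lte(det(E), det(v$cov0[s, s, drop = FALSE]) + 1e-12)
    }
  }
})

test_that("phi_ar is invariant to consistent relabeling of neurons", {
  v <- random_var_model(5, 3)
  p <- phi_partition(list(c(1L, 4L), c(2L, 3L, 5L)))
  r <- phi_ar(v$model, p)
  set.seed(9)
  perm <- sample(5)
  gperm <- gaussian_model(v$cov0[perm, perm], v$covlag[perm, perm], 1)
  pperm <- phi_partition(lapply(p$subsets, function(s) match(s, perm)))
  rperm <- phi_ar(gperm, pperm)
  expect_equal(rperm$phi, r$phi, tolerance = 1e-10)
  expect_equal(rperm$phi_raw, r$phi_raw, tolerance = 1e-10)
})

test_that("estimated phi converges to the analytic value for Gaussian data", {
  v <- random_var_model(4, 21, spectral = 0.7)
  X <- simulate_var(v$A, v$Q, 1e5, seed = 22)
  est <- estimate_gaussian_model(X, 1)
  p <- phi_partition(list(1:2, 3:4))
  expect_equal(phi_ar(est, p)$phi, phi_ar(v$model, p)$phi, tolerance = 0.02)
  # and under the atomic partition too
  pa <- atomic_partition(4)
  expect_equal(phi_ar(est, pa)$phi, phi_ar(v$model, pa)$phi, tolerance = 0.02)
})

test_that("phi_discrete reproduces exact entropy values on tiny systems", {
  # two independent deterministic alternating channels: all conditional
  # entropies vanish, so phi = 0
  st <- rbind(rep(c(0L, 1L), 50), rep(c(1L, 0L), 50))
  b <- binned_matrix(st, 0.03)
  expect_equal(phi_discrete(b, 1, atomic_partition(2)), 0, tolerance = 1e-12)

  # single subset: terms cancel identically
  expect_equal(phi_discrete(b, 1, phi_partition(list(1:2))), 0)

  # node 2 copies node 1's previous state; node 1 is an iid fair coin.
  # Exhaustive enumeration of the 4-state joint gives phi = ln 2.
  set.seed(5)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  st2 <- rbind(x, c(0L, x[-n]))
  b2 <- binned_matrix(st2, 0.03)
  expect_equal(phi_discrete(b2, 1, phi_partition(list(1, 2))), log(2),
               tolerance = 0.01)
  expect_error(phi_discrete(coin_binned(11, 100), 1, atomic_partition(11)),
               "small systems")
})

test_that("discrete and autoregressive phi agree for Gaussianized binary data", {
  # weakly coupled 2-node binary chain: the plug-in discrete value and the
  # AR value are close (exact equality holds only in the Gaussian limit)
  spec <- generator_spec(n_neurons = 2, duration_s = 600, coupling = 0.3,
                         base_rate = 0.3, seed = 13)
  b <- binarize(gen_coupled(spec), 0.03)
  p <- phi_partition(list(1, 2))
  d <- phi_discrete(b, 1, p)
  a <- phi_ar(estimate_gaussian_model(b, 1), p, normalize = FALSE)$phi_raw
  expect_lt(abs(d - a), 0.05)
  expect_gt(d, 0)
})

test_that("phi_result serializes to JSON with partition labels", {
  v <- random_var_model(3, 2)
  r <- phi_ar(v$model, phi_partition(list(1:2, 3)))
  j <- jsonlite::fromJSON(phi_result_json(r))
  expect_equal(j$phi, r$phi)
  expect_equal(j$lag_bins, 1)
  expect_equal(j$partition[[1]], c("n1", "n2"))
})
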