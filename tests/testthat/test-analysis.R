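test_that("period_phi emits one normalized record per period", {
  spec <- generator_spec(n_neurons = 10, duration_s = 960, coupling = 0.4,
                         base_rate = 0.12, seed = 4)
  sess <- gen_session_with_rewards(spec, phi_reward_link = 1)
  rec <- period_phi(sess, list(method = "atomic", lag_bins = 1))
  expect_equal(nrow(rec), 8)
  expect_equal(rec$period_index, 0:7)
  expect_equal(rec$duration_s, rep(120, 8))
  ok <- is.finite(rec$phi_normalized)
  expect_true(all(rec$n_neurons_used[ok] >= 2))
  # reward rate is count / duration: 16-min session, 120 s periods
  n_rew <- nrow(sess$events)
  expect_equal(sum(rec$reward_rate * rec$duration_s), n_rew, tolerance = 1e-9)
  # 4 rewards in a 120 s period would give 1/30 per second
  expect_equal(4 / 120, 1 / 30)
})

test_that("day_average means two sessions and passes singles through", {
  rec <- data.frame(day = c(1, 1, 1, 1, 2, 2),
                    period_index = c(0, 1, 0, 1, 0, 1),
                    phi_normalized = c(0.2, 0.3, 0.4, 0.5, 0.7, NA),
                    reward_rate = c(1, 2, 3, 4, 5, 6) / 30)
  d <- day_average(rec)
  expect_equal(d$phi_normalized[d$day == 1 & d$period_index == 0], 0.3)
  expect_equal(d$phi_normalized[d$day == 1 & d$period_index == 1], 0.4)
  # single-session day passes through; missing values ignored in the mean
  expect_equal(d$phi_normalized[d$day == 2 & d$period_index == 0], 0.7)
  expect_true(is.nan(d$phi_normalized[d$day == 2 & d$period_index == 1]))
})

test_that("spearman_correlation matches hand ranks and the t-based p-value", {
  expect_equal(spearman_correlation(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_correlation(1:4, c(40, 30, 20, 10))$rho, -1)
  r <- spearman_correlation(1:4, c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)  # hand rank computation: 1 - 6*2/(4*15)
  tstat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(r$p_value, 2 * pt(-tstat, df = 2), tolerance = 1e-12)
  # cross-check against the reference rank correlation
  set.seed(14)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(spearman_correlation(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 1:3), "4 complete pairs")
  # incomplete pairs are dropped
  expect_equal(spearman_correlation(c(1:4, NA), c(1, 3, 2, 4, 9))$n, 4)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(15)
  x <- runif(25); y <- runif(25)
  base <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(exp(3 * x), y)$rho, base)
  expect_equal(spearman_correlation(x, log(y + 1))$rho, base)
})

test_that("bonferroni_alpha reproduces the conventional thresholds", {
  expect_equal(bonferroni_alpha(0.05, 15), 1 / 300)
  # conventionally printed as 0.0034 (rounded up); within one ulp of that print
  expect_lt(abs(bonferroni_alpha(0.05, 15) - 0.0034), 1e-4)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_alpha(0.01, 15), 4), 6.667e-4)
})

test_that("correlate_phi_rewards flags significance and ignores row order", {
  set.seed(16)
  rec <- data.frame(phi_normalized = seq(0.01, 0.32, length.out = 32),
                    reward_rate = seq(0.01, 0.32, length.out = 32) + rnorm(32, sd = 0.02))
  rep1 <- correlate_phi_rewards(rec, n_hypotheses = 15)
  expect_equal(rep1$alpha_corrected, 0.05 / 15)
  expect_true(rep1$significant)
  rep2 <- correlate_phi_rewards(rec[sample(32), ], n_hypotheses = 15)
  expect_equal(rep2$rho, rep1$rho)
  # all-equal phi propagates the constant-input error
  expect_error(correlate_phi_rewards(
    data.frame(phi_normalized = rep(0.1, 8), reward_rate = runif(8))),
    "constant")
})

test_that("phi normalization scales as 1/n for fixed raw phi", {
  # definitional: the stored column equals phi / n_neurons_used
  spec <- generator_spec(n_neurons = 6, duration_s = 120, coupling = 0.3,
                         base_rate = 0.15, seed = 21)
  sess <- gen_session_with_rewards(spec, phi_reward_link = 0, n_periods = 2)
  rec <- period_phi(sess, list(method = "atomic", lag_bins = 1, n_periods = 2))
  res <- attr(rec, "phi_results")
  ok <- which(!vapply(res, is.null, logical(1)))[1]
  expect_equal(rec$phi_normalized[ok],
               res[[ok]]$phi / length(res[[ok]]$neurons_used))
})
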