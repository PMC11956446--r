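test_that("grid posteriors under Beta priors match conjugate closed forms", {
  post <- grid_posterior(beta_prior(1, 1), successes = 3, n = 10)
  expect_lt(max(abs(post$density - dbeta(post$grid, 4, 8))), 1e-6)

  # flat spline prior gives the same posterior
  post_sp <- grid_posterior(uniform_spline_prior(), successes = 3, n = 10)
  expect_lt(max(abs(post_sp$density - dbeta(post_sp$grid, 4, 8))), 1e-6)

  # no data returns the prior unchanged
  post0 <- grid_posterior(beta_prior(2, 2), successes = 0, n = 0)
  expect_lt(max(abs(post0$density - dbeta(post0$grid, 2, 2))), 1e-5)

  expect_error(grid_posterior(beta_prior(1, 1), 5, 3), "successes")
  expect_error(grid_posterior(beta_prior(1, 1), -1, 3), "successes")
  expect_error(grid_posterior(beta_prior(1, 1), 1, 3, grid_size = 100), "501")
})

test_that("conjugacy holds across priors and data sizes (property, G = 4001)", {
  cases <- expand.grid(a = c(1, 2.5, 8), b = c(1, 4), n = c(10, 200, 2000))
  for (i in seq_len(nrow(cases))) {
    a <- cases$a[i]; b <- cases$b[i]; n <- cases$n[i]
    s <- round(0.3 * n)
    post <- grid_posterior(beta_prior(a, b), s, n, grid_size = 4001L)
    expect_lt(max(abs(post$density - dbeta(post$grid, a + s, b + n - s))), 1e-5)
  }
})

test_that("posterior sampling is calibrated and reproducible", {
  post <- grid_posterior(beta_prior(1, 1), 3, 10)  # Beta(4, 8)

  draws <- sample_posterior(post, 1e5, seed = 3)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 4 / 12), 3 * mc_se)

  expect_identical(sample_posterior(post, 1000, seed = 9),
                   sample_posterior(post, 1000, seed = 9))

  # near point mass concentrates all draws
  post_pm <- grid_posterior(beta_prior(1, 1), 1e4, 1e4)
  expect_true(all(abs(sample_posterior(post_pm, 1e4, seed = 1) - 1) < 0.02))
})

test_that("ARR sampling agrees with symmetry, separation and convolution", {
  post_a <- grid_posterior(beta_prior(1, 1), 30, 100)
  post_b <- grid_posterior(beta_prior(1, 1), 40, 100)

  # identical posteriors in both arms: P(ARR < 0) = 0.5
  arr_same <- arr_posterior(post_a, post_a, n_draws = 4e4, seed = 2)
  p_same <- tail_prob(arr_same, 0)
  expect_lt(abs(p_same - 0.5), 3 * sqrt(0.25 / 4e4))

  # concentrated, well-separated posteriors
  post_lo <- grid_posterior(beta_prior(1, 1), 20, 200)   # ~0.1
  post_hi <- grid_posterior(beta_prior(1, 1), 80, 200)   # ~0.4
  arr_sep <- arr_posterior(post_lo, post_hi, n_draws = 2e4, seed = 5)
  expect_gt(tail_prob(arr_sep, 0), 0.99)
  expect_gt(oracle_arr_prob_below(post_lo, post_hi, 0), 0.99)

  # sampling matches exact grid convolution
  arr <- arr_posterior(post_a, post_b, n_draws = 4e4, seed = 7)
  p_hat <- tail_prob(arr, 0)
  p_conv <- oracle_arr_prob_below(post_a, post_b, 0)
  expect_lt(abs(p_hat - p_conv), 3 * sqrt(p_conv * (1 - p_conv) / 4e4))

  # draws live on [-1, 1]
  expect_true(all(arr >= -1 & arr <= 1))
})

test_that("tail_prob behaves as an empirical CDF", {
  expect_equal(tail_prob(c(-2, -1, 1, 2), 0), 0.5)
  expect_equal(tail_prob(c(-3, -2, -1), 0), 1)
  expect_error(tail_prob(numeric(0), 0), "nonempty")

  post <- grid_posterior(beta_prior(1, 1), 3, 10)
  draws <- sample_posterior(post, 1e5, seed = 13)
  p_true <- pbeta(0.2, 4, 8)
  expect_lt(abs(tail_prob(draws, 0.2) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 1e5))

  # trichotomy is exact on samples
  arr <- arr_posterior(post, post, n_draws = 1e4, seed = 1)
  expect_equal(tail_prob(arr, 0) + mean(arr > 0) + mean(arr == 0), 1)
})

test_that("HDI matches brute-force shortest-interval search", {
  post <- grid_posterior(beta_prior(1, 1), 3, 10)  # Beta(4, 8)
  draws <- sample_posterior(post, 1e5, seed = 17)
  h <- hdi(draws, 0.95)
  oracle <- oracle_beta_hdi(4, 8, 0.95)
  expect_lt(abs(h$low - oracle[["low"]]), 0.01)
  expect_lt(abs(h$high - oracle[["high"]]), 0.01)

  hg <- hdi(post, 0.95)
  expect_lt(abs(hg$low - oracle[["low"]]), 0.01)
  expect_lt(abs(hg$high - oracle[["high"]]), 0.01)
  expect_true(hg$contiguous)
  expect_gte(hg$mass, 0.95 - 1e-3)
})

test_that("HDI honours coverage edge cases and symmetry", {
  draws <- c(0.1, 0.4, 0.2, 0.9, 0.5)
  h1 <- hdi(draws, 1)
  expect_equal(c(h1$low, h1$high), c(0.1, 0.9))

  post22 <- grid_posterior(beta_prior(2, 2), 0, 0)
  h <- hdi(post22, 0.5)
  expect_lt(abs((h$low + h$high) / 2 - 0.5), 2e-3)

  expect_error(hdi(draws, 0), "coverage")
  expect_error(hdi(draws, -1), "coverage")
  expect_error(hdi(draws, 1.5), "coverage")
})

test_that("HDI width is nondecreasing in coverage and central for symmetric densities", {
  post <- grid_posterior(beta_prior(1, 1), 30, 100)
  draws <- sample_posterior(post, 5e4, seed = 23)
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.994), function(cv) {
    h <- hdi(draws, cv); h$high - h$low
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))

  # symmetric unimodal: HDI == central interval (Beta(12, 12))
  post_sym <- grid_posterior(beta_prior(12, 12), 0, 0)
  h <- hdi(post_sym, 0.9)
  expect_equal(h$low, qbeta(0.05, 12, 12), tolerance = 5e-3)
  expect_equal(h$high, qbeta(0.95, 12, 12), tolerance = 5e-3)
})

test_that("sampled tail probabilities converge to the convolution value", {
  post_a <- grid_posterior(beta_prior(1, 1), 28, 100)
  post_b <- grid_posterior(beta_prior(1, 1), 35, 100)
  p_exact <- oracle_arr_prob_below(post_a, post_b, 0)
  err <- vapply(c(1e3, 1e5), function(n) {
    abs(tail_prob(arr_posterior(post_a, post_b, n_draws = n, seed = 31), 0) - p_exact)
  }, numeric(1))
  # errors scale roughly as N^(-1/2): allow 3 MC SE at each size
  expect_lt(err[1], 3 * sqrt(p_exact * (1 - p_exact) / 1e3))
  expect_lt(err[2], 3 * sqrt(p_exact * (1 - p_exact) / 1e5))
})

test_that("posterior_prob_below matches the closed-form CDF", {
  post <- grid_posterior(beta_prior(2, 3), 10, 40)
  expect_equal(posterior_prob_below(post, 0.25), pbeta(0.25, 12, 33),
               tolerance = 1e-6)
  expect_equal(posterior_prob_below(post, 0), 0)
  expect_equal(posterior_prob_below(post, 1), 1)
})
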