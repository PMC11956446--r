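test_that("beta_from_summary reproduces the mean/ESS parameterisation", {
  expect_equal(unclass(beta_from_summary(0.5, 2))[c("alpha", "beta")],
               list(alpha = 1, beta = 1))
  p <- beta_from_summary(0.3, 10)
  expect_equal(c(p$alpha, p$beta), c(3, 7))
  expect_equal(p$alpha / (p$alpha + p$beta), 0.3)

  expect_error(beta_from_summary(0, 10), "open interval")
  expect_error(beta_from_summary(1.2, 10), "open interval")
  expect_error(beta_from_summary(0.3, 0), "positive")
})

test_that("Beta(10, 40) central interval matches brute-force CDF inversion", {
  p <- beta_from_summary(0.2, 50)
  expect_equal(c(p$alpha, p$beta), c(10, 40))
  oracle <- oracle_beta_central(10, 40, 0.95)
  expect_equal(unname(qbeta(c(0.025, 0.975), p$alpha, p$beta)),
               unname(oracle), tolerance = 1e-5)
})

test_that("elicited_quantiles enforces its invariants", {
  expect_s3_class(elicited_quantiles(c(.1, .5, .9), c(.2, .3, .4)),
                  "elicited_quantiles")
  expect_error(elicited_quantiles(c(.1, .5), c(.2, .3)), "At least 3")
  expect_error(elicited_quantiles(c(.1, .5, .9), c(.2, .2, .4)), "strictly increasing")
  expect_error(elicited_quantiles(c(.1, .9, .5), c(.2, .3, .4)), "strictly increasing")
  expect_error(elicited_quantiles(c(0, .5, .9), c(.2, .3, .4)), "open interval")
  expect_error(elicited_quantiles(c(.1, .5, .9), c(.2, .3, 1)), "open interval")
})

test_that("uniform quantiles recover the flat density", {
  lv <- seq(0.1, 0.9, by = 0.1)
  prior <- fit_spline_prior(tibble::tibble(level = lv, value = lv))
  x <- seq(0, 1, length.out = 1001)
  expect_lt(max(abs(prior_density(prior, x) - 1)), 0.05)
})

test_that("exact Beta(4,16) quantiles are recovered within 0.02 sup-norm", {
  lv <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  prior <- fit_spline_prior(tibble::tibble(level = lv, value = qbeta(lv, 4, 16)))
  x <- seq(0, 1, length.out = 2001)
  expect_lt(max(abs(prior_cdf(prior, x) - pbeta(x, 4, 16))), 0.02)
})

test_that("minimal basis fit reports its least-squares quantile residuals", {
  lv <- c(0.25, 0.5, 0.75)
  df <- tibble::tibble(level = lv, value = qbeta(lv, 3, 5))
  prior <- fit_spline_prior(df, n_basis = 4L, degree = 3L, augment_knots = FALSE)
  expect_true(is.finite(prior$fit$max_abs_quantile_residual))
  expect_equal(nrow(prior$fit$quantile_residuals), 3L)
  # residuals are the fitted-CDF deviations at the elicited values
  Fhat <- prior_cdf(prior, df$value)
  expect_equal(prior$fit$quantile_residuals$residual, Fhat - lv, tolerance = 1e-12)
})

test_that("fitted spline priors satisfy the density invariants", {
  lv <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  cases <- list(c(1, 1), c(2, 8), c(8, 2), c(12, 12), c(4, 16))
  x <- seq(0, 1, length.out = 10001)
  for (ab in cases) {
    prior <- fit_spline_prior(tibble::tibble(level = lv, value = qbeta(lv, ab[1], ab[2])))
    d <- prior_density(prior, x)
    expect_true(all(d >= -1e-12))
    expect_equal(pracma::trapz(x, d), 1, tolerance = 1e-6)
    expect_true(all(diff(prior_cdf(prior, x)) >= -1e-12))
    expect_true(all(prior$coeffs >= 0))
  }
})

test_that("spline CDF recovery holds across the Beta family (property)", {
  lv <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  x <- seq(0, 1, length.out = 1001)
  set.seed(11)
  ab_grid <- rbind(c(1, 1), c(1, 20), c(20, 1), c(20, 20),
                   matrix(runif(12, 1, 20), ncol = 2))
  for (i in seq_len(nrow(ab_grid))) {
    a <- ab_grid[i, 1]; b <- ab_grid[i, 2]
    prior <- fit_spline_prior(tibble::tibble(level = lv, value = qbeta(lv, a, b)),
                              n_basis = 8L)
    expect_lt(max(abs(prior_cdf(prior, x) - pbeta(x, a, b))), 0.03)
  }
})

test_that("discounting follows the informativeness ladder", {
  x <- seq(0, 1, length.out = 501)

  # any prior, uninformative -> exactly flat
  sp <- fit_spline_prior(
    tibble::tibble(level = c(.05, .25, .5, .75, .95),
                   value = qbeta(c(.05, .25, .5, .75, .95), 4, 16)))
  expect_equal(prior_density(discount_prior(sp, "uninformative"), x), rep(1, length(x)))
  bu <- discount_prior(beta_prior(10, 40), "uninformative")
  expect_equal(c(bu$alpha, bu$beta), c(1, 1))

  # Beta low-informative: ESS rescaled, mean preserved
  bl <- discount_prior(beta_prior(10, 40), "low_informative", low_ess = 5)
  expect_equal(c(bl$alpha, bl$beta), c(1, 4))
  expect_equal(bl$alpha / (bl$alpha + bl$beta), 0.2)

  # spline low-informative: equal-weight mixture with the uniform, unit mass
  sl <- discount_prior(sp, "low_informative")
  expect_equal(prior_density(sl, x), 0.5 * prior_density(sp, x) + 0.5,
               tolerance = 1e-12)
  expect_equal(oracle_mass(function(z) prior_density(sl, z)), 1, tolerance = 1e-6)

  # idempotence at the flat end
  su <- discount_prior(sp, "uninformative")
  expect_equal(prior_density(discount_prior(su, "uninformative"), x),
               prior_density(su, x))
})

test_that("the synthetic elicitation panel honours its contracts", {
  lv <- c(0.05, 0.25, 0.5, 0.75, 0.95)

  # zero jitter: every expert reports the exact Beta quantiles
  panel0 <- generate_elicitation_fixture(0.3, 20, n_experts = 3, jitter_sd = 0, seed = 4)
  for (id in unique(panel0$expert_id)) {
    expect_equal(panel0$value[panel0$expert_id == id], qbeta(lv, 6, 14),
                 tolerance = 1e-7)
  }

  # determinism
  p1 <- generate_elicitation_fixture(0.3, 20, n_experts = 5, jitter_sd = 0.1, seed = 7)
  p2 <- generate_elicitation_fixture(0.3, 20, n_experts = 5, jitter_sd = 0.1, seed = 7)
  expect_identical(p1, p2)

  # pooled fit recovers the generating prior mean
  pooled <- fit_spline_prior(p1)
  x <- seq(0, 1, length.out = 2001)
  mean_hat <- pracma::trapz(x, x * prior_density(pooled, x))
  expect_lt(abs(mean_hat - 0.3), 0.05)
})

test_that("basis antiderivative matches independent quadrature", {
  prior <- uniform_spline_prior(n_basis = 9L)
  x <- c(0, 0.013, 0.2, 0.44, 0.5, 0.77, 0.995, 1)
  A_impl <- splinetrial:::basis_cdf_eval(splinetrial:::spline_basis_of(prior), x)
  A_orac <- oracle_basis_cdf(prior$knots, prior$degree, x)
  expect_equal(A_impl, A_orac, tolerance = 1e-12)
})
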