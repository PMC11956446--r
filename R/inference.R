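#' Grid posterior for a binomial event rate
#'
#' Posterior density of a rate on an equally spaced grid over \[0, 1\] under
#' an arbitrary prior (Beta or B-spline) and a binomial likelihood:
#' `density(x) proportional to prior(x) * x^s * (1 - x)^(n - s)`. The
#' unnormalised density is assembled in log space to avoid underflow at large
#' `n`, then trapezoid-normalised. With `n = 0` the posterior is the prior
#' evaluated on the grid.
#'
#' @param prior A `beta_prior` or `spline_prior`.
#' @param successes Number of events, `0 <= successes <= n`.
#' @param n Number of subjects observed.
#' @param grid_size Number of grid points (>= 501).
#' @param prior_log_density Optional precomputed log prior density on the
#'   grid of this size (a performance cache used by the simulation engine;
#'   must match `prior` and `grid_size`).
#' @return An object of class `grid_posterior` with fields `grid`, `density`
#'   and `log_norm` (log normalising constant of the unnormalised product).
#' @examples
#' post <- grid_posterior(beta_prior(1, 1), successes = 3, n = 10)
#' # conjugacy: equals Beta(4, 8)
#' max(abs(post$density - dbeta(post$grid, 4, 8)))
#' @export
grid_posterior <- function(prior, successes, n, grid_size = 2001L,
                           prior_log_density = NULL) {
  if (!is.numeric(successes) || !is.numeric(n) || successes < 0 || n < 0 || successes > n) {
    abort("Counts must satisfy 0 <= successes <= n.")
  }
  if (grid_size < 501L) abort("`grid_size` must be at least 501.")
  grid <- seq(0, 1, length.out = as.integer(grid_size))
  lp <- prior_log_density %||% log(pmax(prior_density(prior, grid), 0))
  ll <- if (n > 0) dbinom(successes, n, grid, log = TRUE) else 0
  lf <- lp + ll
  lf[!is.finite(lf)] <- -Inf
  m <- max(lf)
  if (!is.finite(m)) abort("Posterior density vanished everywhere on the grid.")
  dens <- exp(lf - m)
  h <- grid[2] - grid[1]
  z <- h * (sum(dens) - (dens[1] + dens[length(dens)]) / 2)
  structure(
    list(grid = grid, density = dens / z, log_norm = m + log(z),
         successes = successes, n = n),
    class = "grid_posterior"
  )
}

#' @export
print.grid_posterior <- function(x, ...) {
  cat(sprintf("<grid_posterior> G = %d, data %g/%g, mean %.4f\n",
              length(x$grid), x$successes, x$n, posterior_mean(x)))
  invisible(x)
}

#' Posterior summaries on the grid
#'
#' `posterior_mean()` is the trapezoid-rule mean; `posterior_prob_below()` is
#' the exact grid-CDF probability `P(rate < threshold)` (the quantity the
#' classical stopping rules consume for the discontinuation endpoint).
#'
#' @param post A `grid_posterior`.
#' @param threshold Rate threshold in \[0, 1\].
#' @return A probability (or mean) as a scalar.
#' @export
posterior_prob_below <- function(post, threshold) {
  stopifnot(inherits(post, "grid_posterior"))
  cdf <- grid_cdf(post)
  approx(post$grid, cdf, xout = pmin(pmax(threshold, 0), 1),
         rule = 2, ties = "ordered")$y
}

#' @rdname posterior_prob_below
#' @export
posterior_mean <- function(post) {
  stopifnot(inherits(post, "grid_posterior"))
  h <- post$grid[2] - post$grid[1]
  xf <- post$grid * post$density
  h * (sum(xf) - (xf[1] + xf[length(xf)]) / 2)
}

grid_cdf <- function(post) {
  h <- post$grid[2] - post$grid[1]
  d <- post$density
  cdf <- c(0, cumsum((d[-length(d)] + d[-1]) / 2) * h)
  cdf / cdf[length(cdf)]
}

#' Draw samples from a grid posterior
#'
#' Inverse-CDF sampling with linear interpolation of the trapezoid grid CDF.
#' Reproducible under a fixed seed.
#'
#' @param post A `grid_posterior`.
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` rate samples in \[0, 1\].
#' @export
sample_posterior <- function(post, n_draws, seed) {
  stopifnot(inherits(post, "grid_posterior"), n_draws >= 1)
  cdf <- grid_cdf(post)
  set.seed(seed)
  u <- runif(n_draws)
  idx <- findInterval(u, cdf, all.inside = TRUE)
  step <- cdf[idx + 1L] - cdf[idx]
  frac <- ifelse(step > 0, (u - cdf[idx]) / step, 0)
  post$grid[idx] + frac * (post$grid[idx + 1L] - post$grid[idx])
}

#' Posterior draws of the absolute risk reduction
#'
#' Independent draws from the treatment-arm and control-arm posteriors
#' combined into draws of the ARR `pi_T - pi_C` on \[-1, 1\]. The two arms
#' use separate, deterministically derived substreams of `seed`, so the
#' treatment stream is unchanged by the length of the control stream.
#'
#' @param post_t,post_c `grid_posterior` objects for the treatment and
#'   control event rates.
#' @param n_draws Number of ARR draws.
#' @param seed Integer master seed for the two substreams.
#' @return Numeric vector of ARR draws.
#' @export
arr_posterior <- function(post_t, post_c, n_draws = 20000L, seed = 1L) {
  draws_t <- sample_posterior(post_t, n_draws, derive_seed(seed, 101))
  draws_c <- sample_posterior(post_c, n_draws, derive_seed(seed, 102))
  draws_t - draws_c
}

#' Empirical tail probability of posterior draws
#'
#' Fraction of draws strictly below `threshold`.
#'
#' @param samples Nonempty numeric vector of posterior draws.
#' @param threshold Cut point.
#' @return A probability.
#' @examples
#' tail_prob(c(-0.2, -0.1, 0.1), 0)
#' @export
tail_prob <- function(samples, threshold) {
  if (length(samples) == 0L) abort("`samples` must be nonempty.")
  mean(samples < threshold)
}
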