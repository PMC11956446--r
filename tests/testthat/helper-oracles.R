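# Independent oracles used across the suite. Each deliberately avoids the
# implementation path it checks: quadrature instead of the closed-form
# antiderivative, discrete convolution instead of posterior sampling,
# exhaustive interval search on closed-form quantiles instead of the
# sorted-window HDI.

# Basis CDF by composite Gauss-Legendre quadrature over knot spans.
oracle_basis_cdf <- function(knots, degree, x) {
  n_basis <- length(knots) - degree - 1L
  gl <- pracma::gaussLegendre(8, 0, 1)
  uk <- unique(knots)
  out <- matrix(0, length(x), n_basis)
  for (i in seq_along(x)) {
    brk <- sort(unique(c(uk[uk < x[i]], x[i])))
    acc <- numeric(n_basis)
    if (length(brk) >= 2) {
      for (s in seq_len(length(brk) - 1L)) {
        a <- brk[s]; b <- brk[s + 1L]
        nodes <- a + (b - a) * gl$x
        B <- splines::splineDesign(knots, nodes, ord = degree + 1L, outer.ok = TRUE)
        acc <- acc + (b - a) * colSums(B * gl$w)
      }
    }
    out[i, ] <- acc
  }
  out
}

# Trapezoid integral of a prior/posterior density over [0, 1].
oracle_mass <- function(f, n = 10001L) {
  x <- seq(0, 1, length.out = n)
  pracma::trapz(x, f(x))
}

# P(X_T - X_C < threshold) by discrete convolution of two grid densities.
oracle_arr_prob_below <- function(post_t, post_c, threshold = 0) {
  g <- post_t$grid
  h <- g[2] - g[1]
  pt <- post_t$density * h
  pc <- post_c$density * h
  pt <- pt / sum(pt); pc <- pc / sum(pc)
  # P(T - C < thr) = sum_j pc_j * P(T < thr + c_j)
  cdf_t <- cumsum(pt)
  idx <- findInterval(threshold + g, g)
  p_t_below <- ifelse(idx <= 0, 0, cdf_t[pmin(idx, length(cdf_t))])
  sum(pc * p_t_below)
}

# Shortest interval with the requested mass for a closed-form Beta, by
# exhaustive scan over interval start probabilities.
oracle_beta_hdi <- function(alpha, beta, coverage, n_scan = 20001L) {
  p0 <- seq(0, 1 - coverage, length.out = n_scan)
  lo <- qbeta(p0, alpha, beta)
  hi <- qbeta(p0 + coverage, alpha, beta)
  i <- which.min(hi - lo)
  c(low = lo[i], high = hi[i])
}

# Central credible interval for a Beta by brute-force CDF inversion on a
# dense grid (no qbeta).
oracle_beta_central <- function(alpha, beta, coverage, n = 1e6) {
  x <- seq(0, 1, length.out = n + 1)
  cdf <- pbeta(x, alpha, beta)
  tail <- (1 - coverage) / 2
  c(low = x[which(cdf >= tail)[1]], high = x[which(cdf >= 1 - tail)[1]])
}

# Standard normal CDF through the complementary error function, independent
# of stats::pnorm.
oracle_norm_cdf <- function(z) pracma::erfc(-z / sqrt(2)) / 2

# Literal transcription of the two interim conjunctions, evaluated
# independently of the decision constructor.
oracle_interim_classical <- function(p_eff, p_disc, boundary, futility_prob) {
  if (p_eff > boundary && p_disc > boundary) return("stop_efficacy")
  if (p_eff < futility_prob && p_disc < futility_prob) return("stop_futility")
  "continue"
}
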