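# Clamped B-spline basis on [0, 1] with exact integration.
#
# The basis is the standard clamped (open uniform) B-spline basis: boundary
# knots 0 and 1 repeated degree + 1 times. Two exact identities carry the
# whole module:
#   * unit integrals: int_0^1 B_j = (t_{j+d+1} - t_j) / (d + 1)
#   * antiderivative: int_0^x B_{j,d} = w_j * sum_{l > j} B_{l,d+1}(x), where
#     B_{.,d+1} is the clamped degree-(d+1) basis on the knot vector extended
#     by one extra boundary knot at each end (de Boor).
# Both are verified against independent quadrature in the test suite.

new_bspline_basis <- function(interior, degree = 3L) {
  degree <- as.integer(degree)
  interior <- as.double(interior)
  if (length(interior) && (any(interior <= 0) || any(interior >= 1) || any(diff(interior) <= 0))) {
    abort("Interior knots must be strictly increasing inside (0, 1).")
  }
  knots <- c(rep(0, degree + 1L), interior, rep(1, degree + 1L))
  n_basis <- length(interior) + degree + 1L
  w <- (knots[seq_len(n_basis) + degree + 1L] - knots[seq_len(n_basis)]) / (degree + 1L)
  list(knots = knots, degree = degree, n_basis = n_basis, int_weights = w)
}

# Equally spaced interior knots giving `n_basis` functions, optionally
# augmented with extra knots (deduplicated at min_gap).
equispaced_interior <- function(n_basis, degree) {
  n_int <- n_basis - degree - 1L
  if (n_int < 0L) abort("`n_basis` must be at least `degree + 1`.")
  if (n_int == 0L) return(numeric(0))
  seq(0, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
}

augment_interior <- function(interior, extra, min_gap = 1e-3) {
  all_k <- sort(unique(c(interior, pmin(pmax(extra, min_gap), 1 - min_gap))))
  keep <- c(TRUE, diff(all_k) > min_gap)
  all_k[keep]
}

basis_eval <- function(basis, x) {
  splines::splineDesign(basis$knots, pmin(pmax(x, 0), 1),
                        ord = basis$degree + 1L, outer.ok = TRUE)
}

basis_cdf_eval <- function(basis, x) {
  d <- basis$degree
  knots2 <- c(0, basis$knots, 1)
  B2 <- splines::splineDesign(knots2, pmin(pmax(x, 0), 1),
                              ord = d + 2L, outer.ok = TRUE)
  # reversed cumulative sum over columns: column j gets sum_{l >= j+1} B2_l
  S <- t(apply(B2[, ncol(B2):1, drop = FALSE], 1L, cumsum))[, ncol(B2):1, drop = FALSE]
  A <- S[, -1L, drop = FALSE]
  sweep(A, 2L, basis$int_weights, `*`)
}
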