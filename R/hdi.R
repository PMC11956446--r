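#' Highest posterior density interval
#'
#' The shortest credible interval containing a given posterior mass. On
#' draws (`numeric` method) it is the shortest window of `ceiling(coverage *
#' N)` consecutive sorted draws, deterministic given the draws; ties go to
#' the leftmost window. On a `grid_posterior` it is computed by a density
#' water-level scan: grid points are admitted in order of decreasing density
#' until the requested mass is reached. When the highest-density region
#' splits into more than one interval (possible for multimodal spline
#' posteriors) the grid method returns the bounding interval of the full
#' region with `contiguous = FALSE`; the stopping rules consume that bounding
#' interval, which is the conservative choice for interval-exclusion tests.
#'
#' @param x Posterior draws (numeric vector) or a [grid_posterior()].
#' @param coverage Target mass in (0, 1]; `coverage = 1` gives the sample
#'   range (or full support).
#' @param ... Unused.
#' @return An object of class `hdi_interval` with fields `low`, `high`,
#'   `coverage`, `contiguous` and the realised `mass`.
#' @examples
#' post <- grid_posterior(beta_prior(1, 1), 3, 10)
#' hdi(post, 0.95)
#' hdi(sample_posterior(post, 1e4, seed = 1), 0.95)
#' @export
hdi <- function(x, coverage = 0.95, ...) {
  if (!is.numeric(coverage) || length(coverage) != 1L || coverage <= 0 || coverage > 1) {
    abort("`coverage` must be a single probability in (0, 1].")
  }
  UseMethod("hdi")
}

new_hdi_interval <- function(low, high, coverage, contiguous, mass) {
  structure(
    list(low = low, high = high, coverage = coverage,
         contiguous = contiguous, mass = mass),
    class = "hdi_interval"
  )
}

#' @export
hdi.numeric <- function(x, coverage = 0.95, ...) {
  n <- length(x)
  if (n < 2L) abort("At least two draws are required.")
  xs <- sort.int(x, method = "quick")
  w <- ceiling(coverage * n)
  if (w >= n) {
    return(new_hdi_interval(xs[1], xs[n], coverage, TRUE, 1))
  }
  widths <- xs[w:n] - xs[seq_len(n - w + 1L)]
  i <- which.min(widths)  # leftmost shortest window
  new_hdi_interval(xs[i], xs[i + w - 1L], coverage, TRUE, w / n)
}

#' @export
hdi.grid_posterior <- function(x, coverage = 0.95, ...) {
  g <- x$grid
  d <- x$density
  h <- g[2] - g[1]
  # trapezoid point masses
  pm <- d * h
  pm[c(1L, length(pm))] <- pm[c(1L, length(pm))] / 2
  pm <- pm / sum(pm)
  ord <- order(d, decreasing = TRUE)
  cum <- cumsum(pm[ord])
  k <- which(cum >= coverage)[1]
  if (is.na(k)) k <- length(ord)
  sel <- sort(ord[seq_len(k)])
  contiguous <- all(diff(sel) == 1L)
  new_hdi_interval(g[sel[1]], g[sel[length(sel)]], coverage, contiguous, cum[k])
}

#' @export
print.hdi_interval <- function(x, ...) {
  cat(sprintf("<hdi_interval> [%.4f, %.4f]  coverage %.3f  mass %.4f%s\n",
              x$low, x$high, x$coverage, x$mass,
              if (x$contiguous) "" else "  (bounding interval of split HDR)"))
  invisible(x)
}
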