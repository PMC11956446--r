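#' Sequential design configuration
#'
#' All thresholds and structural constants of the two-look sequential
#' design. The interim look happens once at `ceiling(interim_fraction *
#' n_total)` subjects per arm.
#'
#' Boundary constants: the first-look boundary is specified on the z scale
#' (`c1 = 2.74`, an O'Brien-Fleming-like conservative bound, giving the
#' posterior-probability threshold `Phi(c1) = 0.997`). The final-look
#' threshold is stored directly as the probability `final_prob = 0.976`,
#' the standard final bound of a two-look O'Brien-Fleming design; storing
#' the probability rather than a z value keeps the printed constant exact.
#'
#' @param n_total Planned subjects per arm.
#' @param interim_fraction Fraction of enrolment at the interim, in (0, 1).
#' @param c1 First-look boundary on the z scale.
#' @param final_prob Final-look posterior-probability threshold.
#' @param m Discontinuation acceptability threshold (rate in (0, 1)).
#' @param futility_prob Posterior-probability futility threshold at interim.
#' @param rule_family `"classical"` (posterior-probability rules) or
#'   `"hdi"` (interval-based rules).
#' @param hdi_eff_coverage Coverage of the interim efficacy HDIs
#'   (default `hdi_coverage_from_bound(c1)` = 0.994).
#' @param hdi_fut_coverage Coverage of the interim futility HDIs.
#' @param hdi_final_coverage Coverage of the final-analysis ARR HDI.
#' @param grid_size Posterior grid size.
#' @param n_draws ARR posterior draws per analysis.
#' @return An object of class `design_config`.
#' @examples
#' design_config(n_total = 100)
#' @export
design_config <- function(n_total = 100L,
                          interim_fraction = 0.5,
                          c1 = 2.74,
                          final_prob = 0.976,
                          m = 0.2,
                          futility_prob = 0.5,
                          rule_family = c("classical", "hdi"),
                          hdi_eff_coverage = NULL,
                          hdi_fut_coverage = 0.5,
                          hdi_final_coverage = 0.95,
                          grid_size = 2001L,
                          n_draws = 20000L) {
  rule_family <- match.arg(rule_family)
  hdi_eff_coverage <- hdi_eff_coverage %||% hdi_coverage_from_bound(c1)
  stopifnot(
    n_total >= 4, interim_fraction > 0, interim_fraction < 1,
    m > 0, m < 1, futility_prob >= 0, futility_prob <= 1,
    hdi_eff_coverage > 0, hdi_eff_coverage < 1,
    hdi_fut_coverage > 0, hdi_fut_coverage < 1,
    hdi_final_coverage > 0, hdi_final_coverage < 1,
    final_prob > 0, final_prob < 1
  )
  structure(
    list(
      n_total = as.integer(n_total),
      interim_fraction = interim_fraction,
      c1 = c1,
      interim_prob = phi(c1),
      final_prob = final_prob,
      m = m,
      futility_prob = futility_prob,
      rule_family = rule_family,
      hdi_eff_coverage = hdi_eff_coverage,
      hdi_fut_coverage = hdi_fut_coverage,
      hdi_final_coverage = hdi_final_coverage,
      grid_size = as.integer(grid_size),
      n_draws = as.integer(n_draws)
    ),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  n per arm %d, interim at fraction %.2f (n1 = %d), rules: %s\n",
              x$n_total, x$interim_fraction,
              interim_n(x$n_total, x$interim_fraction), x$rule_family))
  cat(sprintf("  interim boundary Phi(c1 = %.3g) = %.4f; final threshold %.4f\n",
              x$c1, x$interim_prob, x$final_prob))
  cat(sprintf("  futility threshold %.2f; m = %.2f\n", x$futility_prob, x$m))
  cat(sprintf("  HDI coverages: efficacy %.4f, futility %.2f, final %.3f\n",
              x$hdi_eff_coverage, x$hdi_fut_coverage, x$hdi_final_coverage))
  invisible(x)
}

#' Read or write a design configuration as YAML
#'
#' @param path File path.
#' @param config A [design_config()].
#' @return `read_design_yaml()` returns a `design_config`;
#'   `write_design_yaml()` returns `path` invisibly.
#' @export
read_design_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(design_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warn(paste0("Ignoring unknown design fields: ", paste(extra, collapse = ", ")))
  }
  do.call(design_config, raw[intersect(names(raw), known)])
}

#' @rdname read_design_yaml
#' @export
write_design_yaml <- function(config, path) {
  stopifnot(inherits(config, "design_config"))
  out <- unclass(config)
  out$interim_prob <- NULL  # derived from c1 on read
  yaml::write_yaml(out, path, precision = 16L)
  invisible(path)
}
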