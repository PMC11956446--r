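#' Standard normal CDF
#'
#' The boundary constants of the design are expressed as cumulative normal
#' probabilities of z-scale bounds, e.g. `phi(2.74)` = 0.997 (3 dp).
#'
#' @param z Real z value.
#' @return `P(Z <= z)` for standard normal `Z`.
#' @examples
#' phi(0)      # 0.5
#' phi(2.74)   # 0.9969...
#' @export
phi <- function(z) pnorm(z)

#' Two-sided HDI coverage mimicking a one-sided z boundary
#'
#' A one-sided boundary at `Phi(c)` corresponds to a central (highest
#' density, for a symmetric posterior) interval of coverage
#' `1 - 2 * (1 - Phi(c))`; for the first-look bound `c = 2.74` this gives
#' the 0.994 interim efficacy coverage.
#'
#' @param c Positive z-scale bound.
#' @return Coverage in (0, 1).
#' @examples
#' hdi_coverage_from_bound(2.74)       # 0.9939 (0.994 to 3 dp)
#' hdi_coverage_from_bound(1.959964)   # 0.95
#' @export
hdi_coverage_from_bound <- function(c) {
  if (!is.numeric(c) || any(c <= 0)) abort("`c` must be positive.")
  1 - (1 - phi(c)) * 2
}

new_decision <- function(stage, action, evidence) {
  stage <- match.arg(stage, c("interim", "final"))
  action <- match.arg(action, c("stop_efficacy", "stop_futility", "continue",
                                "declare_efficacy", "no_effect"))
  if (stage == "interim" && action %in% c("declare_efficacy", "no_effect")) {
    abort("Interim stage cannot declare a final result.")
  }
  if (stage == "final" && action %in% c("stop_efficacy", "stop_futility", "continue")) {
    abort("Final stage must declare efficacy or no effect.")
  }
  structure(list(stage = stage, action = action, evidence = evidence),
            class = "trial_decision")
}

#' @export
print.trial_decision <- function(x, ...) {
  ev <- purrr::imap_chr(x$evidence, function(v, nm) {
    if (inherits(v, "hdi_interval")) sprintf("%s=[%.3f,%.3f]", nm, v$low, v$high)
    else sprintf("%s=%.4g", nm, v)
  })
  cat(sprintf("<trial_decision> %s: %s  (%s)\n", x$stage, x$action,
              paste(ev, collapse = ", ")))
  invisible(x)
}

#' Classical interim decision
#'
#' Posterior-probability rules at the single interim look. Efficacy stopping
#' requires *both* endpoints to clear the conservative first-look boundary:
#' `P(ARR < 0) > Phi(c1)` and `P(pi_disc < m) > Phi(c1)`. Futility stopping
#' requires both posterior probabilities to fall below `futility_prob`
#' (0.5 by default, calibrated to stop ~25% of no-effect trials at interim).
#' Otherwise the trial continues. All comparisons are strict; boundary ties
#' resolve to the non-stopping action.
#'
#' @param p_eff `P(ARR < 0)`, the posterior probability the treatment
#'   reduces the event rate.
#' @param p_disc `P(pi_disc < m)`, the posterior probability the
#'   discontinuation rate is acceptable.
#' @param config A [design_config()].
#' @return A `trial_decision`.
#' @examples
#' cfg <- design_config()
#' interim_decision_classical(0.999, 0.999, cfg)  # stop_efficacy
#' interim_decision_classical(0.3, 0.3, cfg)      # stop_futility
#' @export
interim_decision_classical <- function(p_eff, p_disc, config) {
  stopifnot(p_eff >= 0, p_eff <= 1, p_disc >= 0, p_disc <= 1)
  b <- config$interim_prob
  action <- if (p_eff > b && p_disc > b) {
    "stop_efficacy"
  } else if (p_eff < config$futility_prob && p_disc < config$futility_prob) {
    "stop_futility"
  } else {
    "continue"
  }
  new_decision("interim", action,
               list(p_eff = p_eff, p_disc = p_disc,
                    boundary = b, futility_prob = config$futility_prob))
}

#' Classical final decision
#'
#' At the end of the trial efficacy is declared on the primary endpoint
#' only: `P(ARR < 0) > final_prob` (0.976 by default).
#'
#' @inheritParams interim_decision_classical
#' @return A `trial_decision`.
#' @export
final_decision_classical <- function(p_eff, config) {
  stopifnot(p_eff >= 0, p_eff <= 1)
  action <- if (p_eff > config$final_prob) "declare_efficacy" else "no_effect"
  new_decision("final", action,
               list(p_eff = p_eff, boundary = config$final_prob))
}

#' HDI-based interim decision
#'
#' Interval rules at the interim look. Efficacy stopping requires the
#' high-coverage (0.994) HDIs to lie entirely on the favourable side of
#' their thresholds: the ARR interval wholly below 0 and the
#' discontinuation interval wholly below `m`. Futility stopping requires
#' the 0.5-coverage HDIs to straddle their thresholds: 0 strictly inside
#' the ARR interval and `m` strictly inside the discontinuation interval.
#' Otherwise the trial continues.
#'
#' @param arr_hdi_eff,disc_hdi_eff [hdi()] intervals at the efficacy
#'   coverage (`hdi_eff_coverage`).
#' @param arr_hdi_fut,disc_hdi_fut [hdi()] intervals at the futility
#'   coverage (`hdi_fut_coverage`).
#' @param config A [design_config()].
#' @return A `trial_decision`.
#' @export
interim_decision_hdi <- function(arr_hdi_eff, disc_hdi_eff,
                                 arr_hdi_fut, disc_hdi_fut, config) {
  m <- config$m
  eff <- arr_hdi_eff$high < 0 && disc_hdi_eff$high < m
  fut <- (arr_hdi_fut$low < 0 && arr_hdi_fut$high > 0) &&
    (disc_hdi_fut$low < m && disc_hdi_fut$high > m)
  action <- if (eff) "stop_efficacy" else if (fut) "stop_futility" else "continue"
  new_decision("interim", action,
               list(arr_hdi_eff = arr_hdi_eff, disc_hdi_eff = disc_hdi_eff,
                    arr_hdi_fut = arr_hdi_fut, disc_hdi_fut = disc_hdi_fut,
                    m = m))
}

#' HDI-based final decision
#'
#' Efficacy is declared when the final-coverage (0.95) ARR HDI lies
#' entirely below 0.
#'
#' @param arr_hdi The final-analysis ARR [hdi()] interval.
#' @param config A [design_config()].
#' @return A `trial_decision`.
#' @export
final_decision_hdi <- function(arr_hdi, config) {
  action <- if (arr_hdi$low < 0 && arr_hdi$high < 0) "declare_efficacy" else "no_effect"
  new_decision("final", action, list(arr_hdi = arr_hdi))
}
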