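#' Tidy a fitted prior
#'
#' `tidy()` on a `spline_prior` returns one row per basis coefficient;
#' `glance()` returns a one-row fit summary. On a `beta_prior`, `tidy()`
#' returns the two shape parameters.
#'
#' @param x A `spline_prior` or `beta_prior`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spline_prior <- function(x, ...) {
  tibble(
    term = paste0("b", seq_len(x$n_basis)),
    coefficient = x$coeffs,
    knot_low = x$knots[seq_len(x$n_basis)],
    knot_high = x$knots[seq_len(x$n_basis) + x$degree + 1L],
    int_weight = x$int_weights
  )
}

#' @rdname tidy.spline_prior
#' @export
glance.spline_prior <- function(x, ...) {
  tibble(
    degree = x$degree,
    n_basis = x$n_basis,
    informativeness = x$informativeness,
    mix_weight = x$mix_weight,
    n_experts = if (!is.null(x$fit)) x$fit$n_experts else NA_integer_,
    max_abs_quantile_residual = if (!is.null(x$fit)) x$fit$max_abs_quantile_residual else NA_real_,
    dense_rmse = if (!is.null(x$fit)) x$fit$dense_rmse else NA_real_
  )
}

#' @rdname tidy.spline_prior
#' @export
tidy.beta_prior <- function(x, ...) {
  tibble(term = c("alpha", "beta"), estimate = c(x$alpha, x$beta))
}

#' Tidy a grid posterior
#'
#' One row per grid point with the posterior density.
#'
#' @param x A [grid_posterior()].
#' @param ... Unused.
#' @return A tibble with columns `rate` and `density`.
#' @export
tidy.grid_posterior <- function(x, ...) {
  tibble(rate = x$grid, density = x$density)
}

#' Tidy a single trial result
#'
#' One row per analysis stage with the decision and headline evidence.
#'
#' @param x A [run_trial()] result.
#' @param ... Unused.
#' @return A tibble with one row per stage.
#' @export
tidy.trial_result <- function(x, ...) {
  stage_row <- function(dec, n_obs, counts) {
    tibble(
      stage = dec$stage,
      action = dec$action,
      n_per_arm = n_obs,
      events_t = counts[["events_t"]],
      events_c = counts[["events_c"]],
      disc = counts[["disc"]],
      p_eff = dec$evidence$p_eff %||% NA_real_,
      p_disc = dec$evidence$p_disc %||% NA_real_
    )
  }
  out <- stage_row(x$interim_decision, x$counts$n1, x$counts$interim)
  if (!is.null(x$final_decision)) {
    out <- dplyr::bind_rows(out,
                            stage_row(x$final_decision, x$counts$n, x$counts$final))
  }
  out
}

#' Tidy operating characteristics
#'
#' `tidy()` returns the long indicator table (estimate and Monte Carlo
#' standard error per indicator); `glance()` returns a one-row summary with
#' scenario and configuration provenance, as written to the OC CSV.
#'
#' @param x A [operating_characteristics()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trial_oc <- function(x, ...) {
  tibble(
    indicator = names(x$estimates),
    estimate = unlist(x$estimates, use.names = FALSE),
    mc_se = unlist(x$mc_se, use.names = FALSE)
  )
}

#' @rdname tidy.trial_oc
#' @export
glance.trial_oc <- function(x, ...) {
  sc <- x$scenario
  cfg <- x$config
  tibble(
    label = sc$label,
    pi_t = sc$pi_t, pi_c = sc$pi_c, pi_disc = sc$pi_disc,
    n_per_arm = sc$n_per_arm,
    rule_family = cfg$rule_family,
    prior_family = x$prior_family,
    prior_informativeness = paste(x$prior_informativeness, collapse = "/"),
    n_sims = x$n_sims,
    p_declare_effect = x$estimates$p_declare_effect,
    fdr = x$estimates$fdr,
    p_true_futility = x$estimates$p_true_futility,
    p_false_futility = x$estimates$p_false_futility,
    p_true_interim_efficacy = x$estimates$p_true_interim_efficacy,
    mc_se_declare = x$mc_se$p_declare_effect,
    interim_prob = cfg$interim_prob,
    final_prob = cfg$final_prob,
    m = cfg$m,
    futility_prob = cfg$futility_prob,
    hdi_eff_coverage = cfg$hdi_eff_coverage,
    hdi_fut_coverage = cfg$hdi_fut_coverage,
    hdi_final_coverage = cfg$hdi_final_coverage
  )
}

#' Tidy a sample-size search
#'
#' `tidy()` returns the power curve (raw and isotonic-smoothed estimates);
#' `glance()` the chosen size.
#'
#' @param x A [sample_size_search()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.power_search <- function(x, ...) x$curve

#' @rdname tidy.power_search
#' @export
glance.power_search <- function(x, ...) {
  tibble(n_selected = x$n_selected, achieved = x$achieved,
         target_power = x$target_power, n_sims = x$n_sims)
}

#' Tidy an HDI interval
#'
#' @param x An [hdi()] interval.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.hdi_interval <- function(x, ...) {
  tibble(low = x$low, high = x$high, coverage = x$coverage,
         mass = x$mass, contiguous = x$contiguous)
}
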