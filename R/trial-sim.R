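#' Simulation scenario (ground truth)
#'
#' The true data-generating rates of a simulated two-arm trial: event rates
#' in the treatment and control arms and the discontinuation rate in the
#' treatment arm. A treatment effect is "real" when `pi_t < pi_c` (lower
#' event rate under treatment).
#'
#' @param pi_t,pi_c True event rates in the treatment and control arms.
#' @param pi_disc True discontinuation rate in the treatment arm.
#' @param n_per_arm Planned subjects per arm (>= 4).
#' @param label Free-text scenario label.
#' @return An object of class `trial_scenario`.
#' @examples
#' trial_scenario(0.2, 0.3, 0.1, n_per_arm = 100)
#' @export
trial_scenario <- function(pi_t, pi_c, pi_disc, n_per_arm, label = "") {
  stopifnot(
    pi_t >= 0, pi_t <= 1, pi_c >= 0, pi_c <= 1,
    pi_disc >= 0, pi_disc <= 1, n_per_arm >= 4
  )
  structure(
    list(pi_t = pi_t, pi_c = pi_c, pi_disc = pi_disc,
         n_per_arm = as.integer(n_per_arm), label = as.character(label)[1]),
    class = "trial_scenario"
  )
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat(sprintf("<trial_scenario>%s pi_T %.3f, pi_C %.3f, pi_disc %.3f, n/arm %d\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$pi_t, x$pi_c, x$pi_disc, x$n_per_arm))
  invisible(x)
}

#' Generate accumulating trial data under a scenario
#'
#' Draws binomial event counts per arm at the interim and final looks, and
#' binomial discontinuation counts in the treatment arm. Enrolment
#' accumulates: the interim subjects are a nested subset of the final
#' sample, so final counts are interim counts plus independent increments.
#'
#' @param scenario A [trial_scenario()].
#' @param config A [design_config()] (supplies the interim fraction; the
#'   scenario's `n_per_arm` is used as the planned size).
#' @param seed Integer seed; counts are reproducible given the seed.
#' @return A list with `n1`, `n` and named interim/final counts.
#' @export
generate_trial_data <- function(scenario, config, seed) {
  n <- scenario$n_per_arm
  n1 <- interim_n(n, config$interim_fraction)
  set.seed(derive_seed(seed, 1))
  events_t1 <- rbinom(1L, n1, scenario$pi_t)
  events_c1 <- rbinom(1L, n1, scenario$pi_c)
  disc_1 <- rbinom(1L, n1, scenario$pi_disc)
  n2 <- n - n1
  events_t <- events_t1 + rbinom(1L, n2, scenario$pi_t)
  events_c <- events_c1 + rbinom(1L, n2, scenario$pi_c)
  disc <- disc_1 + rbinom(1L, n2, scenario$pi_disc)
  list(
    n1 = n1, n = n,
    interim = c(events_t = events_t1, events_c = events_c1, disc = disc_1),
    final = c(events_t = events_t, events_c = events_c, disc = disc)
  )
}

#' Default analysis priors for the three endpoint rates
#'
#' Builds the prior triple (treatment event rate, control event rate,
#' discontinuation rate) used by the operating-characteristics study, in
#' either the parametric (Beta) or semiparametric (B-spline) family at a
#' given informativeness level. The informative stand-ins encode an expert
#' panel whose treatment-rate belief is centred *above* the control belief
#' (`pi_T - pi_C > 0`), so prior-data conflict scenarios (true effect in
#' the opposite direction) are reproducible.
#'
#' Semiparametric informative priors are fitted to a synthetic elicitation
#' panel generated by [generate_elicitation_fixture()] from the same Beta
#' beliefs; parametric priors use the Beta beliefs directly.
#'
#' @param family `"parametric"` or `"semiparametric"`.
#' @param informativeness `"informative"`, `"low_informative"` or
#'   `"uninformative"`.
#' @param means Named rates (`t`, `c`, `disc`) of the informative beliefs.
#' @param ess Effective sample size of the informative beliefs.
#' @param n_experts,jitter_sd,seed Elicitation panel controls
#'   (semiparametric family only).
#' @return A named list of three `trial_prior` objects
#'   (`treatment`, `control`, `disc`).
#' @examples
#' default_trial_priors("parametric", "uninformative")
#' @export
default_trial_priors <- function(family = c("parametric", "semiparametric"),
                                 informativeness = c("uninformative", "low_informative", "informative"),
                                 means = c(t = 0.4, c = 0.3, disc = 0.2),
                                 ess = 20,
                                 n_experts = 5L, jitter_sd = 0.05, seed = 2024L) {
  family <- match.arg(family)
  informativeness <- match.arg(informativeness)
  build <- function(mean, endpoint_seed) {
    if (family == "parametric") {
      discount_prior(beta_from_summary(mean, ess), informativeness)
    } else {
      if (informativeness == "uninformative") return(uniform_spline_prior())
      panel <- generate_elicitation_fixture(mean, ess, n_experts = n_experts,
                                            jitter_sd = jitter_sd,
                                            seed = endpoint_seed)
      discount_prior(fit_spline_prior(panel), informativeness)
    }
  }
  list(
    treatment = build(means[["t"]], derive_seed(seed, 11)),
    control = build(means[["c"]], derive_seed(seed, 12)),
    disc = build(means[["disc"]], derive_seed(seed, 13))
  )
}

# precompute log prior densities on the analysis grid (performance cache)
prior_grid_cache <- function(priors, grid_size) {
  grid <- seq(0, 1, length.out = grid_size)
  purrr::map(priors, ~ log(pmax(prior_density(.x, grid), 0)))
}

#' Run a single sequential trial
#'
#' Generates accumulating data under the scenario, computes interim
#' posteriors for both event rates and the discontinuation rate, applies
#' the configured interim rule (classical posterior-probability or HDI),
#' and — when the trial continues — computes final posteriors on the full
#' sample and applies the final rule on the primary endpoint only.
#'
#' `P(ARR < 0)` is estimated from `config$n_draws` independent posterior
#' draws per arm; `P(pi_disc < m)` and the discontinuation HDIs are exact
#' grid quantities. The discontinuation endpoint is observed in the
#' treatment arm only.
#'
#' @param scenario A [trial_scenario()].
#' @param config A [design_config()].
#' @param priors Named list with elements `treatment`, `control`, `disc`
#'   (see [default_trial_priors()]).
#' @param seed Integer seed for the trial's data and posterior draws.
#' @param .prior_cache Internal: precomputed log prior densities.
#' @return An object of class `trial_result`.
#' @examples
#' cfg <- design_config(n_total = 60)
#' sc <- trial_scenario(0.15, 0.4, 0.1, n_per_arm = 60)
#' run_trial(sc, cfg, default_trial_priors("parametric", "uninformative"), seed = 1)
#' @export
run_trial <- function(scenario, config, priors, seed, .prior_cache = NULL) {
  stopifnot(all(c("treatment", "control", "disc") %in% names(priors)))
  cache <- .prior_cache %||% prior_grid_cache(priors, config$grid_size)
  dat <- generate_trial_data(scenario, config, seed)

  post_t1 <- grid_posterior(priors$treatment, dat$interim[["events_t"]], dat$n1,
                            config$grid_size, prior_log_density = cache$treatment)
  post_c1 <- grid_posterior(priors$control, dat$interim[["events_c"]], dat$n1,
                            config$grid_size, prior_log_density = cache$control)
  post_d1 <- grid_posterior(priors$disc, dat$interim[["disc"]], dat$n1,
                            config$grid_size, prior_log_density = cache$disc)
  arr1 <- arr_posterior(post_t1, post_c1, config$n_draws, derive_seed(seed, 2))

  interim <- if (config$rule_family == "classical") {
    interim_decision_classical(
      p_eff = tail_prob(arr1, 0),
      p_disc = posterior_prob_below(post_d1, config$m),
      config
    )
  } else {
    interim_decision_hdi(
      arr_hdi_eff = hdi(arr1, config$hdi_eff_coverage),
      disc_hdi_eff = hdi(post_d1, config$hdi_eff_coverage),
      arr_hdi_fut = hdi(arr1, config$hdi_fut_coverage),
      disc_hdi_fut = hdi(post_d1, config$hdi_fut_coverage),
      config
    )
  }

  final <- NULL
  if (interim$action == "continue") {
    post_t2 <- grid_posterior(priors$treatment, dat$final[["events_t"]], dat$n,
                              config$grid_size, prior_log_density = cache$treatment)
    post_c2 <- grid_posterior(priors$control, dat$final[["events_c"]], dat$n,
                              config$grid_size, prior_log_density = cache$control)
    arr2 <- arr_posterior(post_t2, post_c2, config$n_draws, derive_seed(seed, 3))
    final <- if (config$rule_family == "classical") {
      final_decision_classical(tail_prob(arr2, 0), config)
    } else {
      final_decision_hdi(hdi(arr2, config$hdi_final_coverage), config)
    }
  }

  structure(
    list(scenario = scenario, config = config, seed = seed,
         counts = dat, interim_decision = interim, final_decision = final),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> seed", x$seed, "\n  interim:", x$interim_decision$action)
  if (!is.null(x$final_decision)) cat("  final:", x$final_decision$action)
  cat("\n")
  invisible(x)
}

#' Did a trial declare a treatment effect?
#'
#' `TRUE` when the trial stopped for efficacy at interim or declared
#' efficacy at the final analysis.
#'
#' @param result A [run_trial()] result.
#' @return Logical scalar.
#' @export
declared_effect <- function(result) {
  result$interim_decision$action == "stop_efficacy" ||
    (!is.null(result$final_decision) &&
       result$final_decision$action == "declare_efficacy")
}

#' Monte Carlo operating characteristics of the design
#'
#' Runs `n_sims` independent trials under one scenario and aggregates the
#' five performance indicators: the proportion of trials declaring the
#' treatment effect (interim or final), the false discovery rate under a
#' null scenario, the proportions of trials truly/falsely stopping for
#' futility at interim, and the proportion truly stopping for efficacy at
#' interim. Ground truth classification: the effect is real iff
#' `pi_t < pi_c`; futility stopping is "true" when `pi_t >= pi_c` or
#' `pi_disc > m`, "false" when the effect is real and the discontinuation
#' rate acceptable. Indicators whose ground-truth condition does not apply
#' to the scenario are `NA`.
#'
#' Each trial uses its own deterministically derived seed, so results are
#' fully reproducible given (`scenario`, `config`, `n_sims`,
#' `master_seed`) and independent of evaluation order.
#'
#' @param scenario A [trial_scenario()].
#' @param config A [design_config()].
#' @param priors Prior triple as in [run_trial()].
#' @param n_sims Number of simulated trials (>= 100).
#' @param master_seed Master seed.
#' @return An object of class `trial_oc`; see [tidy.trial_oc()].
#' @export
operating_characteristics <- function(scenario, config, priors,
                                      n_sims = 2000L, master_seed = 1L) {
  stopifnot(n_sims >= 100)
  cache <- prior_grid_cache(priors, config$grid_size)
  interim_actions <- character(n_sims)
  declared <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    res <- run_trial(scenario, config, priors, derive_seed(master_seed, i),
                     .prior_cache = cache)
    interim_actions[i] <- res$interim_decision$action
    declared[i] <- declared_effect(res)
  }
  effect_real <- scenario$pi_t < scenario$pi_c
  disc_acceptable <- scenario$pi_disc <= config$m
  p_fut <- mean(interim_actions == "stop_futility")
  p_int_eff <- mean(interim_actions == "stop_efficacy")
  p_declare <- mean(declared)
  mc_se <- function(p) sqrt(p * (1 - p) / n_sims)
  est <- list(
    p_declare_effect = p_declare,
    fdr = if (!effect_real) p_declare else NA_real_,
    p_true_futility = if (!effect_real || !disc_acceptable) p_fut else NA_real_,
    p_false_futility = if (effect_real && disc_acceptable) p_fut else NA_real_,
    p_true_interim_efficacy = if (effect_real) p_int_eff else NA_real_,
    p_interim_futility = p_fut,
    p_interim_efficacy = p_int_eff
  )
  structure(
    list(scenario = scenario, config = config, n_sims = n_sims,
         master_seed = master_seed,
         estimates = est,
         mc_se = purrr::map(est, ~ if (is.na(.x)) NA_real_ else mc_se(.x)),
         prior_informativeness = purrr::map_chr(priors, "informativeness"),
         prior_family = if (inherits(priors$treatment, "spline_prior"))
           "semiparametric" else "parametric"),
    class = "trial_oc"
  )
}

#' @export
print.trial_oc <- function(x, ...) {
  cat(sprintf("<trial_oc> %s rules, %s priors, %d sims\n",
              x$config$rule_family, x$prior_family, x$n_sims))
  print(tidy(x))
  invisible(x)
}
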