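# Pipeline commands: thin, file-oriented wrappers over the elicitation,
# simulation and sample-size machinery. Each command is deterministic given
# (inputs, seed) and writes a run manifest next to its outputs. The Rscript
# front-end in inst/cli/trialdesign.R maps subcommands onto these functions.

#' Fit and serialize priors from an elicited quantiles CSV
#'
#' Fits one semiparametric B-spline prior per expert plus a linearly pooled
#' panel prior, and the pooled parametric Beta prior (least-squares Beta fit
#' to the pooled quantile judgements), then writes them as JSON together
#' with fit diagnostics (CDF residuals at the elicited quantiles, density
#' curve data) and a run manifest.
#'
#' @param quantiles_csv Input CSV (see [read_quantiles_csv()]).
#' @param out_dir Output directory (created if missing).
#' @param n_basis,degree Spline basis controls, as in [fit_spline_prior()].
#' @param informativeness Informativeness tag applied to the fitted priors.
#' @return Invisibly, a list with the pooled priors and written file paths.
#' @export
cmd_elicit <- function(quantiles_csv, out_dir,
                       n_basis = 8L, degree = 3L,
                       informativeness = "informative") {
  panel <- read_quantiles_csv(quantiles_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pooled <- fit_spline_prior(panel, n_basis = n_basis, degree = degree,
                             informativeness = informativeness)
  experts <- split(panel, panel$expert_id)
  per_expert <- purrr::imap(experts, function(df, id) {
    fit_spline_prior(df, n_basis = n_basis, degree = degree,
                     informativeness = informativeness)
  })
  pooled_q <- dplyr::summarise(dplyr::group_by(panel, .data$level),
                               value = mean(.data$value), .groups = "drop")
  pf <- beta_quantile_fit(pooled_q$level, pooled_q$value)
  beta_pooled <- beta_prior(pf$alpha, pf$beta, informativeness = informativeness)

  paths <- character(0)
  p <- file.path(out_dir, "prior_pooled_spline.json")
  write_prior_json(pooled, p); paths <- c(paths, p)
  p <- file.path(out_dir, "prior_pooled_beta.json")
  write_prior_json(beta_pooled, p); paths <- c(paths, p)
  for (id in names(per_expert)) {
    p <- file.path(out_dir, sprintf("prior_%s_spline.json", id))
    write_prior_json(per_expert[[id]], p)
    paths <- c(paths, p)
  }

  resid_path <- file.path(out_dir, "fit_residuals.csv")
  readr::write_csv(pooled$fit$quantile_residuals, resid_path)
  x <- seq(0, 1, length.out = 401)
  dens_path <- file.path(out_dir, "density_curves.csv")
  readr::write_csv(dplyr::bind_rows(
    tibble(prior = "pooled_spline", rate = x, density = prior_density(pooled, x)),
    tibble(prior = "pooled_beta", rate = x, density = prior_density(beta_pooled, x))
  ), dens_path)
  paths <- c(paths, resid_path, dens_path)

  write_run_manifest(file.path(out_dir, "manifest.json"), config = NULL,
                     seed = NA, outputs = paths,
                     extra = list(command = "elicit", input = basename(quantiles_csv),
                                  n_basis = n_basis, degree = degree))
  invisible(list(pooled_spline = pooled, pooled_beta = beta_pooled,
                 per_expert = per_expert, files = paths))
}

#' Simulate operating characteristics for a scenario grid
#'
#' Runs the Monte Carlo operating-characteristics study for every row of a
#' scenario CSV under one design configuration, writing one OC row per
#' scenario x prior family x rule family combination requested, plus a
#' run manifest. Thresholds actually used (interim and final probability
#' boundaries, m, HDI coverages) are recorded in every output row.
#'
#' @param scenario_csv Scenario grid CSV (see [read_scenarios_csv()]).
#' @param design_yaml Design configuration YAML
#'   (see [read_design_yaml()]); `NULL` uses defaults.
#' @param n_sims Simulated trials per scenario.
#' @param seed Master seed.
#' @param out_csv Output OC table path.
#' @param prior_family `"parametric"` or `"semiparametric"`.
#' @param informativeness Prior informativeness level.
#' @param rule_family Overrides the configuration's rule family if given.
#' @return The OC tibble, invisibly.
#' @export
cmd_simulate <- function(scenario_csv, design_yaml = NULL, n_sims = 2000L,
                         seed = 1L, out_csv = "oc.csv",
                         prior_family = "parametric",
                         informativeness = "uninformative",
                         rule_family = NULL) {
  scenarios <- read_scenarios_csv(scenario_csv)
  config <- if (is.null(design_yaml)) design_config() else read_design_yaml(design_yaml)
  if (!is.null(rule_family)) config$rule_family <- match.arg(rule_family, c("classical", "hdi"))
  priors <- default_trial_priors(prior_family, informativeness)

  rows <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, ]
    sc <- trial_scenario(row$pi_t, row$pi_c, row$pi_disc, row$n_per_arm,
                         label = row$label)
    cfg <- config
    cfg$n_total <- sc$n_per_arm
    oc <- operating_characteristics(sc, cfg, priors, n_sims = n_sims,
                                    master_seed = derive_seed(seed, i))
    glance(oc)
  })
  oc_table <- dplyr::bind_rows(rows)
  readr::write_csv(oc_table, out_csv)
  write_run_manifest(paste0(out_csv, ".manifest.json"), config = config,
                     seed = seed, outputs = out_csv,
                     extra = list(command = "simulate", n_sims = n_sims,
                                  prior_family = prior_family,
                                  informativeness = informativeness))
  invisible(oc_table)
}

#' Sample-size search over a grid of candidate sizes
#'
#' Wraps [sample_size_search()] for a single scenario described in a YAML
#' file, writing the power curve CSV (columns `n`, `power`, `mc_se`,
#' `power_smoothed`), the chosen size, and a run manifest.
#'
#' @param scenario_yaml YAML with fields `pi_t`, `pi_c`, `pi_disc`
#'   (and optionally `label`).
#' @param design_yaml Design configuration YAML; `NULL` uses defaults.
#' @param target_power Target probability of declaring the effect.
#' @param n_grid Increasing candidate sizes per arm.
#' @param n_sims Simulated trials per candidate.
#' @param seed Master seed.
#' @param out_csv Power curve output path.
#' @inheritParams cmd_simulate
#' @return The `power_search` object, invisibly.
#' @export
cmd_power <- function(scenario_yaml, design_yaml = NULL, target_power = 0.8,
                      n_grid = c(50L, 100L, 150L, 200L), n_sims = 1000L,
                      seed = 1L, out_csv = "power_curve.csv",
                      prior_family = "parametric",
                      informativeness = "uninformative") {
  sc_raw <- yaml::read_yaml(scenario_yaml)
  sc <- trial_scenario(sc_raw$pi_t, sc_raw$pi_c, sc_raw$pi_disc,
                       n_per_arm = n_grid[1], label = sc_raw$label %||% "")
  config <- if (is.null(design_yaml)) design_config() else read_design_yaml(design_yaml)
  priors <- default_trial_priors(prior_family, informativeness)
  ps <- sample_size_search(sc, config, priors, target_power = target_power,
                           n_grid = n_grid, n_sims = n_sims, seed = seed)
  readr::write_csv(ps$curve, out_csv)
  write_run_manifest(paste0(out_csv, ".manifest.json"), config = config,
                     seed = seed, outputs = out_csv,
                     extra = list(command = "power", target_power = target_power,
                                  n_selected = ps$n_selected, achieved = ps$achieved))
  invisible(ps)
}
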