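#' Search the smallest sample size reaching a target power
#'
#' Estimates the probability of declaring the treatment effect at each
#' candidate size by Monte Carlo, smooths the estimated power curve with
#' isotonic regression (power is nondecreasing in `n`; smoothing tames
#' Monte Carlo noise), and returns the smallest candidate whose smoothed
#' power reaches `target_power`. When no candidate qualifies, the chosen
#' size is `NA` and `achieved` is `FALSE`.
#'
#' @param scenario A [trial_scenario()] template; its `n_per_arm` is
#'   replaced by each candidate size.
#' @param config A [design_config()] template (its `n_total` follows the
#'   candidate size).
#' @param priors Prior triple as in [run_trial()].
#' @param target_power Target probability of declaring the effect.
#' @param n_grid Increasing candidate sizes per arm.
#' @param n_sims Simulated trials per candidate size.
#' @param seed Master seed.
#' @return An object of class `power_search` with the chosen size and the
#'   power curve (see [tidy.power_search()]).
#' @export
sample_size_search <- function(scenario, config, priors, target_power = 0.8,
                               n_grid, n_sims = 1000L, seed = 1L) {
  n_grid <- as.integer(n_grid)
  if (length(n_grid) < 1L || any(diff(n_grid) <= 0)) {
    abort("`n_grid` must be strictly increasing.")
  }
  power <- numeric(length(n_grid))
  se <- numeric(length(n_grid))
  for (k in seq_along(n_grid)) {
    sc_k <- trial_scenario(scenario$pi_t, scenario$pi_c, scenario$pi_disc,
                           n_per_arm = n_grid[k], label = scenario$label)
    cfg_k <- config
    cfg_k$n_total <- n_grid[k]
    oc <- operating_characteristics(sc_k, cfg_k, priors, n_sims = n_sims,
                                    master_seed = derive_seed(seed, k))
    power[k] <- oc$estimates$p_declare_effect
    se[k] <- oc$mc_se$p_declare_effect
  }
  smoothed <- if (length(n_grid) > 1L) isoreg(n_grid, power)$yf else power
  hit <- which(smoothed >= target_power)
  structure(
    list(
      curve = tibble(n = n_grid, power = power, mc_se = se,
                     power_smoothed = smoothed),
      target_power = target_power,
      n_selected = if (length(hit)) n_grid[hit[1]] else NA_integer_,
      achieved = length(hit) > 0L,
      n_sims = n_sims, seed = seed
    ),
    class = "power_search"
  )
}

#' @export
print.power_search <- function(x, ...) {
  if (x$achieved) {
    cat(sprintf("<power_search> smallest n/arm reaching power %.2f: %d\n",
                x$target_power, x$n_selected))
  } else {
    cat(sprintf("<power_search> target power %.2f not achieved on the grid\n",
                x$target_power))
  }
  print(x$curve)
  invisible(x)
}
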