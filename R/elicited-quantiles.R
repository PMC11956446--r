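#' Elicited quantiles for an event rate
#'
#' Container for an expert's elicited cumulative judgements about an event
#' rate on (0, 1): a set of probability levels and the rate values the expert
#' attaches to them (e.g. "I am 95% sure the scarring rate is below 0.35").
#'
#' @param levels Probability levels in (0, 1), strictly increasing.
#' @param values Rate values in (0, 1), strictly increasing, same length as
#'   `levels`. At least three pairs are required.
#' @param label Free-text identifier (endpoint and/or expert id).
#' @return An object of class `elicited_quantiles`.
#' @examples
#' elicited_quantiles(c(0.05, 0.5, 0.95), c(0.1, 0.2, 0.35), label = "expert 1")
#' @export
elicited_quantiles <- function(levels, values, label = "") {
  levels <- as.double(levels)
  values <- as.double(values)
  if (length(levels) != length(values)) {
    abort("`levels` and `values` must have the same length.")
  }
  if (length(levels) < 3L) {
    abort("At least 3 elicited quantiles are required.")
  }
  if (any(levels <= 0) || any(levels >= 1) || any(values <= 0) || any(values >= 1)) {
    abort("All levels and values must lie in the open interval (0, 1).")
  }
  if (any(diff(levels) <= 0)) {
    abort("`levels` must be strictly increasing.")
  }
  if (any(diff(values) <= 0)) {
    abort("`values` must be strictly increasing (duplicate or reversed values are degenerate).")
  }
  structure(
    list(levels = levels, values = values, label = as.character(label)[1]),
    class = "elicited_quantiles"
  )
}

#' @export
print.elicited_quantiles <- function(x, ...) {
  cat("<elicited_quantiles>", if (nzchar(x$label)) paste0(" ", x$label) else "", "\n", sep = "")
  print(tibble(level = x$levels, value = x$values))
  invisible(x)
}

#' @export
as_tibble.elicited_quantiles <- function(x, ...) {
  tibble(label = x$label, level = x$levels, value = x$values)
}

#' Coerce a data frame of elicited judgements to `elicited_quantiles`
#'
#' Expects columns `level` and `value`; rows are sorted by level. An optional
#' `expert_id` (or `label`) column must be constant within the frame — use
#' [dplyr::group_split()] or [fit_spline_prior()] directly for multi-expert
#' tables.
#'
#' @param data A data frame with columns `level` and `value`.
#' @param label Overrides the label; defaults to the `expert_id`/`label`
#'   column when present.
#' @return An `elicited_quantiles` object.
#' @export
as_elicited_quantiles <- function(data, label = NULL) {
  if (inherits(data, "elicited_quantiles")) return(data)
  if (!all(c("level", "value") %in% names(data))) {
    abort("`data` must have columns `level` and `value`.")
  }
  lab <- label
  for (cand in c("expert_id", "label")) {
    if (is.null(lab) && cand %in% names(data)) {
      u <- unique(data[[cand]])
      if (length(u) > 1L) {
        abort(sprintf("Column `%s` is not constant; split by expert before coercing.", cand))
      }
      lab <- as.character(u)
    }
  }
  ord <- order(data$level)
  elicited_quantiles(data$level[ord], data$value[ord], label = lab %||% "")
}

#' Generate a synthetic expert elicitation panel
#'
#' Emulates a quantile-judgement elicitation exercise for a binary-endpoint
#' rate: each expert's latent belief is the Beta distribution implied by
#' (`true_dist_mean`, `true_dist_ess`); the reported quantiles are the exact
#' Beta quantiles at `levels`, perturbed by Gaussian noise of standard
#' deviation `jitter_sd` on the logit scale and re-sorted so each expert's
#' judgements stay monotone.
#'
#' @param true_dist_mean Mean of the generating Beta belief, in (0, 1).
#' @param true_dist_ess Effective sample size (alpha + beta) of the belief.
#' @param n_experts Number of experts on the panel.
#' @param jitter_sd Logit-scale standard deviation of expert noise (>= 0);
#'   0 gives every expert the exact Beta quantiles.
#' @param seed Integer seed; the panel is reproducible given the seed.
#' @param levels Probability levels asked of each expert.
#' @return A tibble with columns `expert_id`, `level`, `value`, suitable for
#'   [fit_spline_prior()] or [write_quantiles_csv()].
#' @examples
#' generate_elicitation_fixture(0.3, 20, n_experts = 3, jitter_sd = 0.1, seed = 7)
#' @export
generate_elicitation_fixture <- function(true_dist_mean, true_dist_ess,
                                         n_experts = 5L, jitter_sd = 0.1,
                                         seed = 1L,
                                         levels = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(
    true_dist_mean > 0, true_dist_mean < 1, true_dist_ess > 0,
    n_experts >= 1, jitter_sd >= 0
  )
  alpha <- true_dist_mean * true_dist_ess
  beta <- (1 - true_dist_mean) * true_dist_ess
  q <- qbeta(levels, alpha, beta)
  rows <- purrr::map(seq_len(n_experts), function(e) {
    set.seed(derive_seed(seed, e))
    z <- stats::qlogis(q) + stats::rnorm(length(q), sd = jitter_sd)
    v <- sort(stats::plogis(z))
    # guard against numerically collapsed adjacent quantiles
    v <- pmin(pmax(v + seq_along(v) * 1e-9, 1e-6), 1 - 1e-6)
    tibble(expert_id = paste0("expert_", e), level = levels, value = v)
  })
  dplyr::bind_rows(rows)
}
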