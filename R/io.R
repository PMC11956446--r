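#' Read or write elicited quantiles CSV
#'
#' The interchange format for expert panels: columns `expert_id`, `level`,
#' `value` with a header row; levels and values in (0, 1).
#'
#' @param path CSV file path.
#' @param data A data frame with columns `expert_id`, `level`, `value`.
#' @return `read_quantiles_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
read_quantiles_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("expert_id", "level", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Quantiles CSV %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(df$level) | df$level <= 0 | df$level >= 1 |
                 !is.finite(df$value) | df$value <= 0 | df$value >= 1)
  if (length(bad)) {
    abort(sprintf(
      "Quantiles CSV %s: levels/values outside (0, 1) at data line(s) %s",
      path, paste(head(bad + 1L, 5L), collapse = ", ")))
  }
  df[required]
}

#' @rdname read_quantiles_csv
#' @export
write_quantiles_csv <- function(data, path) {
  readr::write_csv(data[c("expert_id", "level", "value")], path)
  invisible(path)
}

#' Serialize a prior to JSON
#'
#' Spline priors store the degree, knot vector, coefficients,
#' informativeness tag and uniform mixture weight; Beta priors store the
#' two shape parameters. Round-trips are lossless at full double
#' precision.
#'
#' @param prior A `trial_prior`.
#' @param path JSON file path.
#' @return `write_prior_json()` returns `path` invisibly;
#'   `read_prior_json()` returns the prior.
#' @export
write_prior_json <- function(prior, path) {
  payload <- if (inherits(prior, "spline_prior")) {
    list(kind = "spline", degree = prior$degree, knots = prior$knots,
         coeffs = prior$coeffs, informativeness = prior$informativeness,
         mix_weight = prior$mix_weight, label = prior$label)
  } else if (inherits(prior, "beta_prior")) {
    list(kind = "beta", alpha = prior$alpha, beta = prior$beta,
         informativeness = prior$informativeness)
  } else {
    abort("`prior` must be a spline_prior or beta_prior.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_prior_json
#' @export
read_prior_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$kind, "beta")) {
    return(beta_prior(p$alpha, p$beta, informativeness = p$informativeness))
  }
  if (identical(p$kind, "spline")) {
    degree <- as.integer(p$degree)
    interior <- p$knots[p$knots > 0 & p$knots < 1]
    basis <- new_bspline_basis(interior, degree)
    if (basis$n_basis != length(p$coeffs)) {
      abort(sprintf("Corrupt prior JSON %s: %d coefficients for a %d-function basis.",
                    path, length(p$coeffs), basis$n_basis))
    }
    return(new_spline_prior(basis, p$coeffs,
                            informativeness = p$informativeness,
                            mix_weight = p$mix_weight, label = p$label %||% ""))
  }
  abort(sprintf("Unknown prior kind in %s.", path))
}

#' Read a scenario grid CSV
#'
#' Columns: `pi_t`, `pi_c`, `pi_disc`, `n_per_arm`, optional `label`.
#'
#' @param path CSV file path.
#' @return A tibble of scenarios.
#' @export
read_scenarios_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("pi_t", "pi_c", "pi_disc", "n_per_arm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Scenario CSV %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (!"label" %in% names(df)) {
    df$label <- sprintf("scenario_%d", seq_len(nrow(df)))
  }
  df
}

#' Write a run manifest
#'
#' Every tabular output of the pipeline commands is paired with a JSON
#' manifest capturing the configuration snapshot, package version, master
#' seed, timestamp and MD5 digests of the produced files, enabling exact
#' replay and integrity checks.
#'
#' @param path Manifest path.
#' @param config A [design_config()] or NULL.
#' @param seed Master seed used.
#' @param outputs Character vector of produced file paths.
#' @param extra Named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, outputs, extra = list()) {
  digests <- tools::md5sum(outputs)
  manifest <- c(list(
    package = "splinetrial",
    version = as.character(utils::packageVersion("splinetrial")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = seed,
    config = if (!is.null(config)) unclass(config) else NULL,
    outputs = purrr::map2(names(digests), unname(digests),
                          ~ list(file = basename(.x), md5 = .y))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Export posterior draws to CSV
#'
#' Debugging aid: writes a posterior trace (e.g. from [sample_posterior()]
#' or [arr_posterior()]) as a two-column CSV `draw_index`, `value`.
#'
#' @param draws Numeric vector of posterior draws.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  readr::write_csv(tibble(draw_index = seq_along(draws), value = draws), path)
  invisible(path)
}
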