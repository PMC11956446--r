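Package: splinetrial
Title: Bayesian Sequential Two-Endpoint Trial Design with Semiparametric
    B-Spline Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of Bayesian adaptive sequential trials
    with a binary primary endpoint (absolute risk reduction) and a binary
    secondary acceptability endpoint (treatment discontinuation). Provides
    semiparametric prior elicitation from expert quantiles using
    nonnegative B-spline densities, parametric Beta priors with
    informativeness discounting, grid-based posterior inference with
    highest-density-interval computation, classical posterior-probability
    and HDI-based stopping rules with O'Brien-Fleming-like boundaries, and
    a Monte Carlo engine for operating characteristics (power, false
    discovery rate, interim futility and efficacy proportions) and sample
    size search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
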