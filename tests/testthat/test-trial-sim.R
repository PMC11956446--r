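uninf <- default_trial_priors("parametric", "uninformative")

test_that("trial data generation is degenerate-safe, nested and reproducible", {
  cfg <- design_config(n_total = 80)

  sc0 <- trial_scenario(0, 0.3, 0.1, n_per_arm = 80)
  for (seed in 1:20) {
    expect_equal(generate_trial_data(sc0, cfg, seed)$final[["events_t"]], 0)
  }

  sc <- trial_scenario(0.3, 0.4, 0.2, n_per_arm = 80)
  d1 <- generate_trial_data(sc, cfg, 42)
  expect_identical(d1, generate_trial_data(sc, cfg, 42))
  expect_equal(d1$n1, 40L)
  expect_true(all(d1$interim <= d1$final))
  expect_true(all(d1$final <= d1$n))
})

test_that("event counts have the right binomial moments", {
  cfg <- design_config(n_total = 200)
  sc <- trial_scenario(0.3, 0.5, 0.1, n_per_arm = 200)
  n_rep <- 3000
  rates <- vapply(seq_len(n_rep), function(i) {
    generate_trial_data(sc, cfg, i)$final[["events_t"]] / 200
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / 200 / n_rep)
  expect_lt(abs(mean(rates) - 0.3), 3 * se)
})

test_that("extreme separation stops for efficacy at interim almost surely", {
  cfg <- design_config(n_total = 400)
  sc <- trial_scenario(0.01, 0.6, 0.01, n_per_arm = 400)
  stops <- vapply(1:200, function(seed) {
    run_trial(sc, cfg, uninf, seed)$interim_decision$action == "stop_efficacy"
  }, logical(1))
  expect_gt(mean(stops), 0.99)
})

test_that("a true null with HDI rules mostly ends in no_effect", {
  cfg <- design_config(n_total = 100, rule_family = "hdi")
  sc <- trial_scenario(0.3, 0.3, 0.1, n_per_arm = 100)
  actions <- vapply(1:200, function(seed) {
    r <- run_trial(sc, cfg, uninf, seed)
    if (is.null(r$final_decision)) r$interim_decision$action else r$final_decision$action
  }, character(1))
  expect_gt(mean(actions == "no_effect"), 0.5)
  expect_lt(mean(actions %in% c("stop_efficacy", "declare_efficacy")), 0.1)
})

test_that("a full trial trace is byte-stable under a fixed seed", {
  cfg <- design_config(n_total = 60)
  sc <- trial_scenario(0.2, 0.4, 0.15, n_per_arm = 60)
  r1 <- run_trial(sc, cfg, uninf, seed = 2718)
  r2 <- run_trial(sc, cfg, uninf, seed = 2718)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$interim_decision$evidence, r2$interim_decision$evidence)
  # the result stores the full decision trace
  td <- tidy(r1)
  expect_true(all(c("stage", "action", "events_t", "events_c", "disc") %in% names(td)))
})

test_that("trial results honour the stage contract", {
  cfg <- design_config(n_total = 60)
  sc <- trial_scenario(0.3, 0.3, 0.2, n_per_arm = 60)
  for (seed in 1:30) {
    r <- run_trial(sc, cfg, uninf, seed)
    if (r$interim_decision$action == "continue") {
      expect_false(is.null(r$final_decision))
      expect_true(r$final_decision$action %in% c("declare_efficacy", "no_effect"))
    } else {
      expect_null(r$final_decision)
    }
  }
})

test_that("operating characteristics are reproducible and internally consistent", {
  cfg <- design_config(n_total = 60)
  sc <- trial_scenario(0.2, 0.45, 0.1, n_per_arm = 60)
  oc1 <- operating_characteristics(sc, cfg, uninf, n_sims = 150, master_seed = 9)
  oc2 <- operating_characteristics(sc, cfg, uninf, n_sims = 150, master_seed = 9)
  expect_identical(tidy(oc1), tidy(oc2))

  est <- oc1$estimates
  props <- unlist(est[!is.na(est)])
  expect_true(all(props >= 0 & props <= 1))
  expect_equal(oc1$mc_se$p_declare_effect,
               sqrt(est$p_declare_effect * (1 - est$p_declare_effect) / 150))
  # effect real here: fdr and true-futility slots are NA, false-futility is not
  expect_true(is.na(est$fdr))
  expect_true(is.na(est$p_true_futility))
  expect_false(is.na(est$p_false_futility))
})

test_that("small and large Monte Carlo runs agree within combined error", {
  cfg <- design_config(n_total = 80)
  sc <- trial_scenario(0.25, 0.45, 0.1, n_per_arm = 80)
  oc_s <- operating_characteristics(sc, cfg, uninf, n_sims = 100, master_seed = 21)
  oc_l <- operating_characteristics(sc, cfg, uninf, n_sims = 1000, master_seed = 22)
  for (ind in c("p_declare_effect", "p_interim_futility", "p_interim_efficacy")) {
    diff_est <- abs(oc_s$estimates[[ind]] - oc_l$estimates[[ind]])
    comb <- sqrt(max(oc_s$mc_se[[ind]], 1e-3)^2 + max(oc_l$mc_se[[ind]], 1e-3)^2)
    expect_lt(diff_est, 3.5 * comb)
  }
})

test_that("null interim efficacy is bounded by the nominal boundary level", {
  cfg <- design_config(n_total = 100)
  sc <- trial_scenario(0.3, 0.3, 0.1, n_per_arm = 100)
  oc <- operating_characteristics(sc, cfg, uninf, n_sims = 1000, master_seed = 77)
  p <- oc$estimates$p_interim_efficacy
  bound <- 1 - phi(cfg$c1)
  expect_lte(p, bound + 3 * sqrt(bound * (1 - bound) / 1000))
})

test_that("sample size search finds trivial answers and a monotone curve", {
  cfg <- design_config()
  pri <- uninf

  # huge effect: the smallest candidate already qualifies
  sc_big <- trial_scenario(0.05, 0.6, 0.05, n_per_arm = 40)
  ps_big <- sample_size_search(sc_big, cfg, pri, target_power = 0.8,
                               n_grid = c(40L, 80L), n_sims = 150, seed = 5)
  expect_true(ps_big$achieved)
  expect_equal(ps_big$n_selected, 40L)

  # null effect: never achieved
  sc_null <- trial_scenario(0.3, 0.3, 0.05, n_per_arm = 40)
  ps_null <- sample_size_search(sc_null, cfg, pri, target_power = 0.8,
                                n_grid = c(40L, 80L), n_sims = 150, seed = 6)
  expect_false(ps_null$achieved)
  expect_true(is.na(ps_null$n_selected))

  expect_error(sample_size_search(sc_big, cfg, pri, n_grid = c(80L, 40L)),
               "increasing")
})

test_that("derived seeds stay in the 32-bit range and separate streams", {
  seeds <- derive_seed(123456, 0:5000)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 2))
  expect_true(is.integer(seeds))
  # no collisions across a realistic number of trial replicates
  expect_equal(anyDuplicated(seeds), 0L)
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
})
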