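test_that("outcome tables are internally consistent and null effects vanish", {
  run <- cached_run("cochrane")
  ot <- run$outcomes
  expect_equal(ot$difference, ot$probiotic - ot$control)
  expect_equal(ot$pct_difference, 100 * ot$difference / ot$control)
  expect_true(all(ot$difference <= 0))

  led_null <- run_paired_simulation(
    run$population, run$model, duration_model(7.4), null_scenario(), seed = 2L
  )
  ot0 <- outcome_table(led_null)
  expect_identical(ot0$difference, rep(0, 4))
  expect_error(
    outcome_table(structure(list(episodes = run$ledger$episodes[0, ]),
                            class = "episode_ledger")),
    "no episodes"
  )
})

test_that("subgroup shares are exhaustive over partitions and 100% for the whole cohort", {
  run <- cached_run("yhec")
  sg_all <- subgroup_attribution(run$ledger, run$population, subgroups = "all")
  expect_equal(sg_all$pct_population, 100)
  expect_equal(sg_all$pct_avoided_days, 100)
  expect_equal(sg_all$pct_cost_savings, 100)

  parts <- subgroup_attribution(run$ledger, run$population,
                                subgroups = c("children", "adults"))
  expect_equal(sum(parts$pct_avoided_days), 100, tolerance = 1e-6)
  expect_equal(sum(parts$pct_cost_savings), 100, tolerance = 1e-6)
  vac <- subgroup_attribution(run$ledger, run$population,
                              subgroups = c("unvaccinated", "vaccinated"))
  expect_equal(sum(vac$pct_avoided_days), 100, tolerance = 1e-6)

  expect_error(subgroup_attribution(run$ledger, run$population, "smokers"),
               "unknown subgroup")
})

test_that("children contribute more avoided days than their population share", {
  run <- cached_run("yhec", sample_rate = 1 / 8000)
  sg <- subgroup_attribution(run$ledger, run$population, "children")
  expect_gt(sg$pct_avoided_days, sg$pct_population)
})

test_that("one-way sensitivity reproduces closed-form bounds and the base case", {
  cfg <- small_config("yhec", sample_rate = 1 / 16000, seed = 1L)
  ranges <- data.frame(parameter = "scenario.duration_reduction_days",
                       base = 0.77, lower = 0.04, upper = 1.5)
  sens <- one_way_sensitivity(cfg, ranges)
  base_run <- cached_run("yhec", sample_rate = 1 / 16000, seed = 1L)
  ctrl_days <- base_run$outcomes$control[base_run$outcomes$outcome == "rti_days"]

  pct <- 100 * sens$avoided_rti_days / ctrl_days
  lower_pct <- pct[sens$bound == "lower"]
  upper_pct <- pct[sens$bound == "upper"]
  # duration scaling is exact under paired draws: reduction = bound / 7.4
  expect_lt(abs(lower_pct - 100 * 0.04 / 7.4), 0.3)
  expect_lt(abs(upper_pct - 100 * 1.5 / 7.4), 1)

  # a bound equal to the base value reproduces the base case exactly
  degenerate <- data.frame(parameter = "scenario.duration_reduction_days",
                           base = 0.77, lower = 0.77, upper = 0.77)
  sens0 <- one_way_sensitivity(cfg, degenerate)
  expect_identical(sens0$avoided_rti_days[sens0$bound == "lower"],
                   sens0$avoided_rti_days[sens0$parameter == "base_case"])

  expect_error(
    one_way_sensitivity(cfg, data.frame(parameter = "scenario.not_a_field",
                                        base = 1, lower = 1, upper = 1)),
    "unknown config path"
  )
})

test_that("antibiotic rate-ratio bounds shift course reductions as the oracle predicts", {
  cfg <- small_config("yhec", sample_rate = 1 / 4000, seed = 6L)
  for (bound in c(0.45, 0.94)) {
    cfg2 <- cfg
    cfg2$scenario$antibiotic_rr <- bound
    run <- run_burden_model(cfg2)
    red <- -run$outcomes$pct_difference[run$outcomes$outcome == "antibiotic_courses"]
    expect_lt(abs(red - 100 * 0.554 * (1 - bound)), 3)
  }
})

test_that("convergence reporting requires a real design and tracks Monte-Carlo scaling", {
  cfg <- small_config("yhec", seed = 30L)
  expect_error(convergence_test(cfg, sample_rates = 1 / 16000), "two sample rates")
  expect_error(convergence_test(cfg, sample_rates = c(1 / 16000, 1 / 8000),
                                replicates = 1), "three replicates")

  rep <- convergence_test(cfg, sample_rates = c(1 / 64000, 1 / 8000),
                          replicates = 8)
  tab <- rep$table
  expect_true(is.logical(rep$converged))
  expect_setequal(unique(tab$n_persons), round(329256000 * c(1 / 64000, 1 / 8000)))
  cv_small <- tab$cv_pct[tab$sample_rate == 1 / 64000 & tab$outcome == "avoided_rti_days"]
  cv_large <- tab$cv_pct[tab$sample_rate == 1 / 8000 & tab$outcome == "avoided_rti_days"]
  # Monte-Carlo noise shrinks with cohort size (~1/sqrt(N))
  expect_gt(cv_small, cv_large)
})
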