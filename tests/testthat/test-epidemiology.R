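calibrated_toy_model <- function(profile = seasonal_profile("flat"),
                                 risk = risk_effects()) {
  incidence_model(profile = profile, base_daily_hazard = 2e-4,
                  vaccinated_rate_ratio = 0.9, risk = risk)
}

test_that("seasonal profiles normalize and peak where requested", {
  flat <- seasonal_profile("flat")
  expect_length(flat, 365)
  expect_equal(as.numeric(flat), rep(1 / 365, 365))
  wp <- seasonal_profile("winter_peak", peak_day = 35, concentration = 3)
  expect_equal(sum(wp), 1)
  expect_true(all(wp >= 0))
  expect_equal(which.max(wp), 35)
  expect_error(seasonal_profile("winter_peak", concentration = -1), ">= 0")
})

test_that("the daily hazard factorizes over the printed rate ratios", {
  m <- calibrated_toy_model()
  base_person <- make_person(age = 35L, vaccinated = FALSE)
  expect_equal(effective_daily_hazard(base_person, 100, m), 2e-4)

  passive <- make_person(age = 35L, passive_smoker = TRUE)
  expect_equal(effective_daily_hazard(passive, 100, m) /
                 effective_daily_hazard(base_person, 100, m), 1.15)

  home_child <- make_person(age = 8L)
  school_child <- make_person(age = 8L, in_school = TRUE)
  expect_equal(effective_daily_hazard(school_child, 100, m) /
                 effective_daily_hazard(home_child, 100, m), 1.22)
  expect_equal(effective_daily_hazard(home_child, 100, m) /
                 effective_daily_hazard(base_person, 100, m), 2.85)

  office <- make_person(age = 35L, employed = TRUE, office_shared = TRUE)
  expect_equal(effective_daily_hazard(office, 100, m) /
                 effective_daily_hazard(base_person, 100, m), 1.07)

  vacc <- make_person(age = 35L, vaccinated = TRUE)
  expect_equal(effective_daily_hazard(vacc, 100, m) /
                 effective_daily_hazard(base_person, 100, m), 0.9)

  expect_error(effective_daily_hazard(base_person, 0, m), "1..365")
  expect_error(effective_daily_hazard(base_person, 366, m), "1..365")
  expect_error(
    effective_daily_hazard(base_person, 10, incidence_model()),
    "not calibrated"
  )
})

test_that("mean episode duration combines base, smoking and scenario factors", {
  dm <- duration_model(base_mean_days = 7.4)
  risk <- risk_effects()
  expect_equal(mean_duration(make_person(), dm, risk), 7.4)
  expect_equal(mean_duration(make_person(active_smoker = TRUE), dm, risk),
               7.4 * 1.168)
  expect_equal(mean_duration(make_person(passive_smoker = TRUE), dm, risk),
               7.4 * 1.045)
  expect_equal(mean_duration(make_person(), dm, risk, 1 - 0.77 / 7.4), 6.63)
  expect_error(mean_duration(make_person(), dm, risk, 0), "0, 1")
})

test_that("duration sampling is mean-exact, monotone and scale-invariant", {
  dm <- duration_model(7.4, dispersion = 0.45)
  # degenerate dispersion returns the mean for any draw
  dm0 <- duration_model(7.4, dispersion = 0)
  expect_equal(sample_duration(7.4, dm0, c(0.01, 0.5, 0.99)), rep(7.4, 3))

  u <- withr::with_seed(42, runif(1e5))
  d <- sample_duration(7.4, dm, u)
  expect_gt(mean(d), 7.33)
  expect_lt(mean(d), 7.47)
  expect_true(all(d >= dm$minimum_days))

  # monotone in the draw; exact scale family at a common draw
  expect_true(all(diff(sample_duration(7.4, dm, c(0.1, 0.4, 0.8))) > 0))
  u0 <- c(0.2, 0.5, 0.9)
  expect_equal(sample_duration(7.4 * 0.8959, dm, u0),
               sample_duration(7.4, dm, u0) * 0.8959)
  expect_error(sample_duration(-1, dm, 0.5), "> 0")
})

test_that("calibration hits a homogeneous-cohort closed form", {
  # homogeneous unvaccinated adults, flat profile, deterministic durations:
  # an independent renewal recursion over 365 days must reproduce the target
  pop <- make_person(n = 2000, age = 35L, vaccinated = FALSE)
  dm <- duration_model(base_mean_days = 6, dispersion = 0)
  target <- 900
  m <- incidence_model(
    profile = seasonal_profile("flat"),
    risk = risk_effects(modifiers = FALSE),
    calibration_target_episodes = target,
    target_unvaccinated_episode_share = 1,
    reference_cohort_size = nrow(pop)
  )
  cal <- calibrate_incidence(pop, m, dm)
  # brute force, written independently of the package internals
  p_day <- 1 - exp(-cal$base_daily_hazard)
  at_risk <- 1
  returns <- numeric(365 + 10)
  expected <- 0
  for (day in 1:365) {
    onsets <- at_risk * p_day
    expected <- expected + onsets
    returns[day + 6] <- returns[day + 6] + onsets  # ceil(6) = 6 suppressed days
    at_risk <- at_risk - onsets + returns[day + 1]
  }
  expect_lt(abs(nrow(pop) * expected / target - 1), 0.001)
})

test_that("default-cohort calibration meets both targets and implies the expected vaccination ratio", {
  run <- cached_run("yhec", sample_rate = 1 / 8000)
  cal <- run$calibration
  expect_lt(abs(cal$episode_residual), 1e-5)
  expect_lt(abs(cal$share_residual), 1e-5)
  # share target 0.554 with 53.7% unvaccinated implies r ~ 0.934
  implied <- (0.5370 * (1 - 0.554)) / ((1 - 0.5370) * 0.554)
  expect_lt(abs(run$model$vaccinated_rate_ratio - implied), 0.02)
  expect_error(
    calibrate_incidence(run$population, run$model, duration_model(),
                        max_iter = 1),
    "convergence"
  )
})

test_that("headline reductions are insensitive to the seasonal profile shape", {
  spec <- default_scenarios()$cochrane
  oracle <- expected_reduction_days(spec)
  reds <- sapply(c("flat", "winter_peak"), function(preset) {
    cfg <- small_config("cochrane", sample_rate = 1 / 4000, seed = 5L)
    cfg$epidemiology$profile$preset <- preset
    run <- run_burden_model(cfg)
    -run$outcomes$pct_difference[run$outcomes$outcome == "rti_days"]
  })
  expect_lt(abs(reds[["flat"]] - reds[["winter_peak"]]), 1.5)
  expect_lt(abs(reds[["flat"]] - oracle), 1)
  expect_lt(abs(reds[["winter_peak"]] - oracle), 1)
})
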