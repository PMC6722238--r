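test_that("default scenario effect sets resolve to the published multipliers", {
  sc <- default_scenarios()
  unvacc_adult <- make_person(age = 35L, vaccinated = FALSE, employed = TRUE)
  vacc_adult <- make_person(age = 35L, vaccinated = TRUE, employed = TRUE)
  child <- make_person(age = 8L, vaccinated = FALSE)

  y <- effect_set(unvacc_adult, sc$yhec, "probiotic", uptake_draw = 0.3)
  expect_equal(y$incidence_mult, 1)
  expect_equal(y$duration_mult, 1 - 0.77 / 7.4)
  expect_equal(y$antibiotic_mult, 0.65)
  expect_equal(y$absence_mult, 1 - 0.87 / 1.7)

  # YHEC: duration and absence effects apply to vaccinated users too, the
  # antibiotic effect does not
  yv <- effect_set(vacc_adult, sc$yhec, "probiotic", uptake_draw = 0.3)
  expect_equal(yv$duration_mult, 1 - 0.77 / 7.4)
  expect_equal(yv$antibiotic_mult, 1)
  expect_equal(yv$absence_mult, 1 - 0.87 / 1.7)

  co <- effect_set(unvacc_adult, sc$cochrane, "probiotic", uptake_draw = 0.3)
  expect_equal(co$incidence_mult, 0.70)
  expect_equal(co$duration_mult, 1 - 1.89 / 8.82)
  expect_equal(co$antibiotic_mult, 0.65)

  # Cochrane-sourced effects are excluded for vaccinated persons
  cov <- effect_set(vacc_adult, sc$cochrane, "probiotic", uptake_draw = 0.3)
  expect_equal(cov$incidence_mult, 1)
  expect_equal(cov$duration_mult, 1)
  expect_equal(cov$antibiotic_mult, 1)

  cc <- effect_set(child, sc$yhec, "probiotic", uptake_draw = 0.3)
  expect_equal(cc$absence_mult, 1 - 0.26 / 0.5)
})

test_that("control arm and non-users always receive identity effect sets", {
  people <- make_person(n = 4, age = c(8L, 30L, 30L, 70L),
                        vaccinated = c(FALSE, TRUE, FALSE, FALSE),
                        employed = c(FALSE, TRUE, TRUE, FALSE))
  for (spec in default_scenarios()) {
    ctrl <- effect_set(people, spec, "control", uptake_draw = 0)
    expect_true(all(ctrl == 1))
  }
  # current-intake scenario: a draw above the uptake fraction means non-user
  spec_current <- default_scenarios()$cochrane
  spec_current$uptake_fraction <- 0.044
  nonuser <- effect_set(people, spec_current, "probiotic", uptake_draw = 0.5)
  expect_true(all(nonuser == 1))
  user <- effect_set(make_person(vaccinated = FALSE), spec_current,
                     "probiotic", uptake_draw = 0.01)
  expect_equal(user$incidence_mult, 0.70)
})

test_that("multipliers never exceed one for any person or scenario", {
  people <- make_person(
    n = 8, age = c(3L, 8L, 14L, 20L, 40L, 40L, 70L, 85L),
    vaccinated = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    employed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    active_smoker = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    nursing_home = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  for (spec in c(default_scenarios(), list(null_scenario()))) {
    for (draw in c(0.0, 0.5, 0.999)) {
      es <- effect_set(people, spec, "probiotic", uptake_draw = draw)
      expect_true(all(es > 0 & es <= 1))
    }
  }
})

test_that("standardized mean differences convert to the base-case day reductions", {
  expect_identical(smd_to_days(0.17, 5.1), 0.87)
  expect_identical(smd_to_days(0.17, 1.5), 0.26)
  expect_identical(smd_to_days(-0.17, 5.1), 0.87)
  expect_equal(smd_to_days(0.17, 5.1, digits = Inf), 0.867)
})

test_that("invalid scenario parameters are rejected", {
  expect_error(scenario_spec(incidence_rr = 0), "rate ratios")
  expect_error(scenario_spec(duration_reduction_days = 8, base_mean_days = 7.4),
               "below the base mean")
  expect_error(scenario_spec(uptake_fraction = 1.5), "uptake")
})
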