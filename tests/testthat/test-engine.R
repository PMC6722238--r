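# Engine behaviour is checked on a reduced cohort (1/16,000 sample,
# ~20,600 persons, ~1,500 control episodes) where runs take about a second.

test_that("a null intervention leaves the two arms byte-identical", {
  run <- cached_run("yhec")  # reuse population and calibrated model
  obj <- run$model
  dm <- duration_model(7.4, dispersion = 0.45)
  led <- run_paired_simulation(run$population, obj, dm, null_scenario(), seed = 9L)
  ctrl <- arm_rows(led, "control")
  prob <- arm_rows(led, "probiotic")
  prob$arm <- "control"
  expect_identical(as.data.frame(ctrl), as.data.frame(prob))
})

test_that("paired runs are reproducible for a seed and differ across seeds", {
  run <- cached_run("yhec")
  dm <- duration_model(7.4, dispersion = 0.45)
  spec <- default_scenarios()$yhec
  l1 <- run_paired_simulation(run$population, run$model, dm, spec, seed = 4L)
  l2 <- run_paired_simulation(run$population, run$model, dm, spec, seed = 4L)
  l3 <- run_paired_simulation(run$population, run$model, dm, spec, seed = 5L)
  expect_identical(as.data.frame(l1$episodes), as.data.frame(l2$episodes))
  expect_false(nrow(l1$episodes) == nrow(l3$episodes) &&
                 identical(l1$episodes$duration, l3$episodes$duration))
  expect_error(
    run_paired_simulation(run$population, incidence_model(), dm, spec),
    "calibrated"
  )
})

test_that("YHEC pairing keeps episodes and scales durations exactly", {
  run <- cached_run("yhec")
  eps <- run$ledger$episodes
  ctrl <- eps[eps$arm == "control", ]
  prob <- eps[eps$arm == "probiotic", ]
  # no incidence effect + shared draws: the very same episodes in both arms
  expect_equal(nrow(prob), nrow(ctrl))
  expect_identical(prob$person_id, ctrl$person_id)
  expect_identical(prob$onset_day, ctrl$onset_day)
  # duration multiplier applies to every user's episode, mean-exactly
  expect_equal(prob$duration, ctrl$duration * (1 - 0.77 / 7.4))
  # antibiotic thinning is monotone under common random numbers
  expect_true(all(ctrl$had_antibiotic[prob$had_antibiotic]))
  # other-medication use is unaffected by the intervention
  expect_identical(prob$had_other_medication, ctrl$had_other_medication)
  expect_true(all(eps$pcp_visits == 1L))
  expect_true(all(eps$onset_day >= 1 & eps$onset_day <= 365))
  expect_true(all(eps$duration > 0))
})

test_that("common random numbers give per-person monotone outcomes under Cochrane", {
  run <- cached_run("cochrane")
  eps <- run$ledger$episodes
  ctrl <- eps[eps$arm == "control", ]
  prob <- eps[eps$arm == "probiotic", ]
  nc <- table(factor(ctrl$person_id, levels = unique(ctrl$person_id)))
  np <- table(factor(prob$person_id, levels = unique(ctrl$person_id)))
  expect_true(all(np <= nc))
  # every probiotic episode is a retained control episode with shorter or
  # equal duration and no extra antibiotic course
  key_p <- paste(prob$person_id, prob$episode_index)
  key_c <- paste(ctrl$person_id, ctrl$episode_index)
  expect_true(all(key_p %in% key_c))
  match_c <- match(key_p, key_c)
  expect_true(all(prob$duration <= ctrl$duration[match_c] + 1e-12))
  expect_true(all(ctrl$had_antibiotic[match_c][prob$had_antibiotic]))
  expect_true(all(prob$missed_days <= ctrl$missed_days[match_c] + 1e-12))
})

test_that("Cochrane-sourced effects leave vaccinated persons' disease course unchanged", {
  run <- cached_run("cochrane")
  eps <- run$ledger$episodes
  v_ctrl <- eps[eps$arm == "control" & eps$vaccinated, ]
  v_prob <- eps[eps$arm == "probiotic" & eps$vaccinated, ]
  cols <- c("person_id", "episode_index", "onset_day", "duration",
            "had_antibiotic", "had_other_medication")
  expect_identical(as.data.frame(v_ctrl[, cols, with = FALSE]),
                   as.data.frame(v_prob[, cols, with = FALSE]))
})

test_that("missed work days accrue only to employees and children", {
  for (scenario in c("yhec", "cochrane")) {
    eps <- cached_run(scenario)$ledger$episodes
    ineligible <- !eps$employed & !eps$is_child
    expect_true(all(eps$missed_days[ineligible] == 0))
    expect_true(all(eps$missed_days >= 0))
  }
})

test_that("the two-part absence model reproduces its expected means", {
  n <- 1e5
  draws <- withr::with_seed(21, list(u_any = runif(n), u_amount = runif(n)))
  emp <- make_person(n = n, age = 35L, employed = TRUE)
  identity_eff <- list(absence_mult = 1)
  miss <- sample_absence(emp, identity_eff, draws = draws)
  expect_lt(abs(mean(miss) / (0.42 * 1.7) - 1), 0.02)

  # probiotic arm scales the conditional mean by 1 - 0.87/1.7
  miss_p <- sample_absence(emp, list(absence_mult = 1 - 0.87 / 1.7), draws = draws)
  cond <- miss_p[miss_p > 0]
  expect_lt(abs(mean(cond) / (1.7 - 0.87) - 1), 0.02)

  retired <- make_person(n = 10, age = 70L)
  expect_equal(sample_absence(retired, identity_eff,
                              draws = list(u_any = 0.1, u_amount = 0.5)),
               rep(0, 10))
})
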