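# Shared fixtures: small configurations, hand-built person tables, and a
# run cache so expensive paired simulations are computed once per test run.

.rtisim_cache <- new.env(parent = emptyenv())

small_config <- function(scenario = "yhec", sample_rate = 1 / 16000, seed = 1L) {
  cfg <- default_run_config(scenario, seed = seed)
  cfg$population$sample_rate <- sample_rate
  cfg
}

# Memoized pipeline run keyed by scenario/seed/rate.
cached_run <- function(scenario = "yhec", seed = 1L, sample_rate = 1 / 16000) {
  key <- paste(scenario, seed, format(sample_rate, digits = 12), sep = "|")
  if (is.null(.rtisim_cache[[key]])) {
    .rtisim_cache[[key]] <- run_burden_model(small_config(scenario, sample_rate, seed))
  }
  .rtisim_cache[[key]]
}

# Full 1/1,000-sample runs used by the acceptance checks.
full_runs <- function(scenario, seeds) {
  lapply(seeds, function(s) cached_run(scenario, seed = s, sample_rate = 1 / 1000))
}

# Hand-built one-or-more-person table with explicit attribute flags.
make_person <- function(n = 1, age = 35L, is_female = FALSE, vaccinated = FALSE,
                        active_smoker = FALSE, passive_smoker = FALSE,
                        in_school = FALSE, employed = FALSE,
                        office_shared = FALSE, nursing_home = FALSE) {
  pop <- data.table::data.table(
    person_id = seq_len(n),
    age = as.integer(rep_len(age, n)),
    is_female = rep_len(is_female, n),
    vaccinated = rep_len(vaccinated, n),
    active_smoker = rep_len(active_smoker, n),
    passive_smoker = rep_len(passive_smoker, n),
    in_school = rep_len(in_school, n),
    employed = rep_len(employed, n),
    office_shared = rep_len(office_shared, n),
    nursing_home = rep_len(nursing_home, n)
  )
  pop$shared_indoor <- pop$in_school | (pop$employed & pop$office_shared) | pop$nursing_home
  pop$is_child <- pop$age <= 15L
  data.table::setattr(pop, "class", c("person_table", class(pop)))
  pop
}

# A scenario with every probiotic effect switched off (null intervention).
null_scenario <- function() {
  scenario_spec(
    name = "null", incidence_rr = 1, duration_reduction_days = 0,
    base_mean_days = 7.4, antibiotic_rr = 1,
    absent_reduction_adult_days = 0, absent_reduction_child_days = 0
  )
}

arm_rows <- function(ledger, a) ledger$episodes[ledger$episodes$arm == a, ]
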