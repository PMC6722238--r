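# Configuration, pipeline driver, report writing and the command-line entry
# point. All base-case parameter values live in default_run_config() so no
# constant is buried in simulation code.

#' Default run configuration
#'
#' A nested list holding every model parameter of the base case:
#' population block (cohort structure and prevalences), epidemiology block
#' (seasonal profile, calibration targets, risk-factor effects, duration
#' dispersion), scenario block (probiotic effects and applicability),
#' absenteeism and cost blocks, and the seed. The base case excludes the
#' smoking/school/office risk-factor effects
#' (`epidemiology$include_risk_modifiers = FALSE`); set the flag to `TRUE`
#' for subgroup analyses conditioned on risk-factor effects.
#'
#' @param scenario `"yhec"` or `"cochrane"`.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(scenario = c("yhec", "cochrane"), seed = 1L) {
  scenario <- match.arg(scenario)
  sc <- default_scenarios()[[scenario]]
  list(
    population = list(
      sample_rate = 1 / 1000,
      reference_total = 329256000,
      female_fraction = 0.508,
      unvaccinated_prob = 0.5370,
      active_smoker_share = 0.1250,
      active_smoker_min_age = 12L,
      passive_smoker_prob = 0.2659,
      employment_rate_16plus = 0.58,
      school_enrollment_prob_1_15 = 0.95,
      nursing_home_prob_65plus = 0.03,
      shared_office_prob_employed = 0.758,
      child_age_cutoff = 15L
    ),
    epidemiology = list(
      profile = list(preset = "winter_peak", peak_day = 35L, concentration = 2),
      calibration_target_episodes = 24671,
      target_unvaccinated_episode_share = 0.554,
      reference_cohort_size = 329256,
      include_risk_modifiers = FALSE,
      risk = list(
        passive_smoke_incidence_rr = 1.15,
        school_incidence_rr = 1.22,
        shared_office_incidence_rr = 1.07,
        active_smoke_duration_mult = 1.168,
        passive_smoke_duration_mult = 1.045,
        child_adult_incidence_ratio = 2.85
      ),
      duration = list(dispersion = 0.45, minimum_days = 0.5)
    ),
    scenario = unclass(sc),
    absenteeism = list(
      employee_absence_prob = 0.42, employee_mean_days = 1.7,
      employee_sd_days = 5.1,
      child_absence_prob = 0.18, child_mean_days = 0.5, child_sd_days = 1.5
    ),
    costs = list(
      pcp_payer = 74.16, pcp_copay = 25,
      abx_prescription_prob = 0.29,
      abx_cost_child = 2.95, abx_cost_adult = 3.54,
      abx_child_age_max = 14L, abx_copay = 0,
      othermed_prob = 0.5662, othermed_payer = 26.59, othermed_copay = 11,
      productivity_per_day = 217.92,
      projection_factor = 1000
    ),
    seed = as.integer(seed)
  )
}

# Recursive merge of a user config into defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    stop("load_run_config: expected a block at '", path, "'", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("load_run_config: unknown config field(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_run_config <- function(config) {
  check01 <- function(x, what) {
    if (!is.numeric(x) || !is.finite(x) || x < 0 || x > 1) {
      stop("run_config: ", what, " must lie in [0, 1]", call. = FALSE)
    }
  }
  pb <- config$population
  for (f in c("unvaccinated_prob", "active_smoker_share", "passive_smoker_prob",
              "employment_rate_16plus", "school_enrollment_prob_1_15",
              "nursing_home_prob_65plus", "shared_office_prob_employed",
              "female_fraction")) {
    check01(pb[[f]], paste0("population.", f))
  }
  if (pb$sample_rate <= 0) stop("run_config: population.sample_rate must be > 0", call. = FALSE)
  cb <- config$costs
  for (f in c("pcp_payer", "pcp_copay", "abx_cost_child", "abx_cost_adult",
              "abx_copay", "othermed_payer", "othermed_copay",
              "productivity_per_day")) {
    if (!is.numeric(cb[[f]]) || cb[[f]] < 0) {
      stop("run_config: costs.", f, " must be >= 0", call. = FALSE)
    }
  }
  check01(cb$abx_prescription_prob, "costs.abx_prescription_prob")
  check01(cb$othermed_prob, "costs.othermed_prob")
  check01(config$scenario$uptake_fraction, "scenario.uptake_fraction")
  check01(config$epidemiology$target_unvaccinated_episode_share,
          "epidemiology.target_unvaccinated_episode_share")
  if (config$epidemiology$calibration_target_episodes <= 0) {
    stop("run_config: epidemiology.calibration_target_episodes must be > 0", call. = FALSE)
  }
  invisible(config)
}

#' Load a run configuration from a YAML/JSON file
#'
#' Reads a structured text file, fills unspecified fields from the base-case
#' defaults, rejects unknown keys, and validates ranges. An empty file
#' yields the full base-case defaults.
#'
#' @param path File path (YAML; JSON is a YAML subset and also parses).
#' @param scenario Scenario supplying the defaults for fields the file does
#'   not set; a `scenario.name` field in the file wins.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path, scenario = "yhec") {
  if (!file.exists(path)) {
    stop("load_run_config: file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (!is.null(user$scenario$name)) scenario <- user$scenario$name
  if (!scenario %in% c("yhec", "cochrane")) {
    stop("load_run_config: scenario.name must be 'yhec' or 'cochrane'", call. = FALSE)
  }
  config <- merge_config(default_run_config(scenario), user)
  validate_run_config(config)
  config
}

# Build module objects from config blocks.
config_population <- function(config) {
  pb <- config$population
  population_config(
    sample_rate = pb$sample_rate, reference_total = pb$reference_total,
    female_fraction = pb$female_fraction,
    unvaccinated_prob = pb$unvaccinated_prob,
    active_smoker_share = pb$active_smoker_share,
    active_smoker_min_age = pb$active_smoker_min_age,
    passive_smoker_prob = pb$passive_smoker_prob,
    employment_rate_16plus = pb$employment_rate_16plus,
    school_enrollment_prob_1_15 = pb$school_enrollment_prob_1_15,
    nursing_home_prob_65plus = pb$nursing_home_prob_65plus,
    shared_office_prob_employed = pb$shared_office_prob_employed,
    child_age_cutoff = pb$child_age_cutoff,
    seed = config$seed
  )
}

config_objects <- function(config) {
  eb <- config$epidemiology
  # modifiers = FALSE zeroes the five risk-factor effects but keeps the
  # configured child/adult incidence ratio (base-case structure)
  risk <- do.call(risk_effects, c(eb$risk, list(modifiers = eb$include_risk_modifiers)))
  profile <- seasonal_profile(eb$profile$preset, eb$profile$peak_day,
                              eb$profile$concentration)
  spec <- do.call(scenario_spec, config$scenario)
  dm <- duration_model(base_mean_days = spec$base_mean_days,
                       dispersion = eb$duration$dispersion,
                       minimum_days = eb$duration$minimum_days)
  inc <- incidence_model(
    profile = profile, risk = risk,
    calibration_target_episodes = eb$calibration_target_episodes,
    target_unvaccinated_episode_share = eb$target_unvaccinated_episode_share,
    reference_cohort_size = eb$reference_cohort_size
  )
  absent <- do.call(absenteeism_params, config$absenteeism)
  costs <- do.call(cost_params, config$costs)
  list(risk = risk, inc = inc, dm = dm, spec = spec, absent = absent,
       costs = costs)
}

#' Run the full burden-model pipeline for one configuration
#'
#' Generates the cohort, calibrates the incidence model, runs the paired
#' simulation and aggregates outcomes and costs.
#'
#' @param config A `run_config` list ([default_run_config()] or
#'   [load_run_config()]).
#' @return An object of class `rti_run`: list with `config`, `population`
#'   (the cohort), `population_summary`, `model` (calibrated incidence
#'   model), `calibration` (residuals and iterations), `ledger`,
#'   `outcomes` (the four-row outcome table) and `costs` (a
#'   `cost_summary`).
#' @examples
#' \donttest{
#' cfg <- default_run_config("yhec")
#' cfg$population$sample_rate <- 1 / 20000  # small demonstration cohort
#' run <- run_burden_model(cfg)
#' run$outcomes
#' }
#' @export
run_burden_model <- function(config = default_run_config()) {
  validate_run_config(config)
  obj <- config_objects(config)
  pop <- generate_population(config_population(config))
  inc <- calibrate_incidence(pop, obj$inc, obj$dm)
  # engine draws from an offset stream so cohort and disease-history draws
  # do not share a seed
  ledger <- run_paired_simulation(
    pop, inc, obj$dm, obj$spec, obj$absent, obj$costs,
    seed = config$seed + 1000003L
  )
  run <- list(
    config = config,
    population = pop,
    population_summary = summarize_population(pop),
    model = inc,
    calibration = attr(inc, "calibration"),
    ledger = ledger,
    outcomes = outcome_table(ledger),
    costs = aggregate_costs(ledger, obj$costs)
  )
  class(run) <- "rti_run"
  run
}

#' @export
print.rti_run <- function(x, ...) {
  cat(sprintf("<rti_run> scenario '%s', %d persons, seed %d\n",
              x$ledger$scenario, x$ledger$n_pop, x$config$seed))
  cat(sprintf("calibration: %d iterations, episode residual %.2e\n",
              x$calibration$iterations, x$calibration$episode_residual))
  print(x$outcomes)
  cat(sprintf("national savings: payer %.2f M USD, societal %.2f M USD\n",
              x$costs$national["savings", "payer"] / 1e6,
              x$costs$national["savings", "societal"] / 1e6))
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes `outcomes.csv` (the four-row outcome table), `costs.json`
#' (sample- and national-scale cost totals and savings), and
#' `run_metadata.json` (seed, scenario, cohort size, calibration residuals
#' and a configuration hash for provenance). Numeric outputs are unrounded.
#'
#' @param run An `rti_run`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "rti_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    outcomes = file.path(dir, "outcomes.csv"),
    costs = file.path(dir, "costs.json"),
    metadata = file.path(dir, "run_metadata.json")
  )
  write.csv(run$outcomes, paths[["outcomes"]], row.names = FALSE)
  cost_list <- list(
    sample = cbind(row = rownames(run$costs$sample), run$costs$sample),
    national = cbind(row = rownames(run$costs$national), run$costs$national),
    projection_factor = run$costs$projection_factor
  )
  jsonlite::write_json(cost_list, paths[["costs"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  meta <- list(
    scenario = run$ledger$scenario,
    seed = run$config$seed,
    n_pop = run$ledger$n_pop,
    uptake_fraction = run$ledger$uptake_fraction,
    calibration = run$calibration,
    config_hash = rlang::hash(run$config)
  )
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# -- command-line interface ---------------------------------------------------

cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      stop("flag ", a, " needs a value", call. = FALSE)
    }
    flags[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

cli_config <- function(flags) {
  scenario <- flags$scenario %||% "yhec"
  if (!scenario %in% c("yhec", "cochrane")) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  config <- if (!is.null(flags$config)) {
    load_run_config(flags$config, scenario = scenario)
  } else {
    default_run_config(scenario)
  }
  if (!is.null(flags$scenario)) {
    config$scenario <- unclass(default_scenarios()[[scenario]])
  }
  if (!is.null(flags$seed)) config$seed <- as.integer(flags$seed)
  if (!is.null(flags[["sample-rate"]])) {
    config$population$sample_rate <- as.numeric(flags[["sample-rate"]])
  }
  if (!is.null(flags$uptake)) {
    config$scenario$uptake_fraction <- switch(flags$uptake,
      generalized = 1.0, current = 0.044, none = 0.0,
      stop("unknown uptake: ", flags$uptake, call. = FALSE)
    )
  }
  validate_run_config(config)
  config
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (paired run; writes `outcomes.csv`, `costs.json`
#' and run metadata), `oracle` (closed-form expected values as JSON),
#' `sensitivity` (one-way sweep as CSV), `subgroups` (subgroup attribution
#' as CSV) and `convergence`. Flags: `--config`, `--scenario`
#' (`yhec`/`cochrane`), `--seed`, `--sample-rate`, `--uptake`
#' (`generalized`/`current`/`none`), `--out` (output directory, default
#' `.`). Installed alongside the package as `inst/cli/rtisim.R`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: rtisim <simulate|oracle|sensitivity|subgroups|convergence> [--flags]",
                                call. = FALSE)
    cmd <- args[1]
    flags <- cli_parse_flags(args[-1])
    out_dir <- flags$out %||% "."
    config <- cli_config(flags)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

    if (cmd == "simulate") {
      run <- run_burden_model(config)
      write_run_outputs(run, out_dir)
      print(run)
    } else if (cmd == "oracle") {
      spec <- do.call(scenario_spec, config$scenario)
      oi <- oracle_inputs(
        unvaccinated_episode_share = config$epidemiology$target_unvaccinated_episode_share,
        control_episodes = config$epidemiology$calibration_target_episodes,
        costs = do.call(cost_params, config$costs),
        absent = do.call(absenteeism_params, config$absenteeism)
      )
      vals <- c(
        list(
          pct_reduction_days = expected_reduction_days(spec, oi$unvaccinated_episode_share),
          pct_reduction_episodes = expected_reduction_episodes(spec, oi$unvaccinated_episode_share),
          pct_reduction_antibiotics = expected_reduction_antibiotics(spec, oi$unvaccinated_episode_share)
        ),
        expected_savings(spec, oi)
      )
      path <- file.path(out_dir, "oracle.json")
      jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
      cat(jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
    } else if (cmd == "sensitivity") {
      sens <- one_way_sensitivity(config)
      write.csv(sens, file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
    } else if (cmd == "subgroups") {
      run <- run_burden_model(config)
      sg <- subgroup_attribution(run$ledger, run$population,
                                 cp = do.call(cost_params, config$costs))
      write.csv(sg, file.path(out_dir, "subgroups.csv"), row.names = FALSE)
    } else if (cmd == "convergence") {
      rep <- convergence_test(config,
                              sample_rates = c(config$population$sample_rate / 4,
                                               config$population$sample_rate))
      write.csv(rep$table, file.path(out_dir, "convergence.csv"), row.names = FALSE)
    } else {
      stop("unknown subcommand: ", cmd, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("rtisim error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
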