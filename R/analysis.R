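# Outcome tables, subgroup attribution, one-way sensitivity sweeps, and
# convergence diagnostics.

#' Arm-level outcome table
#'
#' Four event outcomes — RTI episodes, RTI days, antibiotic courses, missed
#' work days — as probiotic-arm total, control-arm total, absolute
#' difference (probiotic minus control, so reductions are negative) and
#' percent difference relative to the control arm.
#'
#' @param ledger An `episode_ledger`.
#' @return data.frame with columns `outcome`, `probiotic`, `control`,
#'   `difference`, `pct_difference`.
#' @export
outcome_table <- function(ledger) {
  stopifnot(inherits(ledger, "episode_ledger"))
  eps <- ledger$episodes
  arm_totals <- function(a) {
    e <- eps[eps$arm == a, ]
    c(rti_episodes = nrow(e),
      rti_days = sum(e$duration),
      antibiotic_courses = sum(e$had_antibiotic),
      missed_work_days = sum(e$missed_days))
  }
  ctrl <- arm_totals("control")
  if (ctrl[["rti_episodes"]] == 0) {
    stop("outcome_table: control arm has no episodes", call. = FALSE)
  }
  prob <- arm_totals("probiotic")
  diff <- prob - ctrl
  data.frame(
    outcome = names(ctrl),
    probiotic = unname(prob),
    control = unname(ctrl),
    difference = unname(diff),
    pct_difference = 100 * unname(diff) / unname(ctrl),
    row.names = NULL
  )
}

subgroup_definitions <- list(
  all = function(pop) rep(TRUE, nrow(pop)),
  children = function(pop) pop$is_child,
  adults = function(pop) !pop$is_child,
  active_smokers = function(pop) pop$active_smoker,
  passive_smokers = function(pop) pop$passive_smoker,
  shared_indoor = function(pop) pop$shared_indoor,
  unvaccinated = function(pop) !pop$vaccinated,
  vaccinated = function(pop) pop$vaccinated
)

#' Subgroup attribution of avoided RTI days and cost savings
#'
#' For each subgroup: its share of the model population, its share of
#' avoided RTI days, and its share of total societal cost savings, all
#' computed from paired per-person differences between the arms. Shares
#' over a partition of the cohort sum to 100%.
#'
#' @param ledger An `episode_ledger`.
#' @param pop The `person_table` the ledger was simulated from.
#' @param subgroups Character vector of subgroup names (any of `"all"`,
#'   `"children"`, `"adults"`, `"active_smokers"`, `"passive_smokers"`,
#'   `"shared_indoor"`, `"unvaccinated"`, `"vaccinated"`).
#' @param cp A [cost_params()] for the societal-cost component.
#' @return data.frame with columns `subgroup`, `pct_population`,
#'   `pct_avoided_days`, `pct_cost_savings`.
#' @export
subgroup_attribution <- function(ledger, pop,
                                 subgroups = c("children", "active_smokers",
                                               "passive_smokers", "shared_indoor",
                                               "unvaccinated"),
                                 cp = cost_params()) {
  stopifnot(inherits(ledger, "episode_ledger"))
  unknown <- setdiff(subgroups, names(subgroup_definitions))
  if (length(unknown)) {
    stop("subgroup_attribution: unknown subgroup(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  eps <- copy(ledger$episodes)
  cb <- cost_episode(eps, cp)
  eps[, soc := cb$payer + cb$copay + cb$productivity]
  per <- eps[, .(days = sum(duration), soc = sum(soc)), by = .(person_id, arm)]
  wide <- dcast(per, person_id ~ arm, value.var = c("days", "soc"), fill = 0)
  for (col in c("days_control", "days_probiotic", "soc_control", "soc_probiotic")) {
    if (!col %in% names(wide)) wide[, (col) := 0]
  }
  saved_days <- wide$days_control - wide$days_probiotic
  saved_soc <- wide$soc_control - wide$soc_probiotic
  tot_days <- sum(saved_days)
  tot_soc <- sum(saved_soc)

  rows <- lapply(subgroups, function(g) {
    flag <- subgroup_definitions[[g]](pop)
    in_g <- flag[wide$person_id]
    data.frame(
      subgroup = g,
      pct_population = 100 * mean(flag),
      pct_avoided_days = if (tot_days == 0) 0 else 100 * sum(saved_days[in_g]) / tot_days,
      pct_cost_savings = if (tot_soc == 0) 0 else 100 * sum(saved_soc[in_g]) / tot_soc
    )
  })
  do.call(rbind, rows)
}

#' Default one-way sensitivity ranges
#'
#' The base-case, lower and upper values of the parameters varied one at a
#' time: the probiotic duration reduction, antibiotic rate ratio and (for
#' the Cochrane scenario) incidence rate ratio at their 95% confidence
#' bounds; the absenteeism reductions; the other-medication probability;
#' antibiotic course costs at +/-50%; and the PCP payer fee at the
#' fee-schedule code bounds (total cost 69.64–124.44 USD with a fixed 25
#' USD copayment).
#'
#' @param scenario `"yhec"` or `"cochrane"`.
#' @return data.frame with columns `parameter` (a config path), `base`,
#'   `lower`, `upper`.
#' @export
default_sensitivity_ranges <- function(scenario = "yhec") {
  common <- data.frame(
    parameter = c("scenario.antibiotic_rr",
                  "scenario.absent_reduction_adult_days",
                  "scenario.absent_reduction_child_days",
                  "costs.othermed_prob",
                  "costs.abx_cost_child",
                  "costs.abx_cost_adult",
                  "costs.pcp_payer"),
    base = c(0.65, 0.87, 0.26, 0.5662, 2.95, 3.54, 74.16),
    lower = c(0.45, 0.153, 0.045, 0.50, 1.48, 1.77, 44.64),
    upper = c(0.94, 1.581, 0.465, 0.60, 4.43, 5.31, 99.44)
  )
  dur <- if (scenario == "cochrane") {
    data.frame(parameter = c("scenario.duration_reduction_days", "scenario.incidence_rr"),
               base = c(1.89, 0.70), lower = c(1.75, 0.50), upper = c(2.03, 0.84))
  } else {
    data.frame(parameter = "scenario.duration_reduction_days",
               base = 0.77, lower = 0.04, upper = 1.5)
  }
  out <- rbind(dur, common)
  if (any(out$lower > out$base | out$base > out$upper)) {
    stop("default_sensitivity_ranges: lower <= base <= upper violated", call. = FALSE)
  }
  out
}

# Set a dotted config path, e.g. "scenario.duration_reduction_days".
set_config_path <- function(config, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (i in seq_along(parts[-length(parts)])) {
    if (is.null(node[[parts[i]]])) {
      stop("set_config_path: unknown config path: ", path, call. = FALSE)
    }
    node <- node[[parts[i]]]
  }
  if (!utils::tail(parts, 1) %in% names(node)) {
    stop("set_config_path: unknown config path: ", path, call. = FALSE)
  }
  config[[parts]] <- value
  config
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the paired simulation with each parameter at its lower and upper
#' bound (all other parameters at base, same seed, so parameter effects are
#' not confounded with Monte-Carlo noise) and reports the two key outcomes:
#' avoided RTI days (sample scale) and saved total societal cost (national
#' scale).
#'
#' @param config A run configuration, see [default_run_config()].
#' @param ranges data.frame with columns `parameter` (dotted config path),
#'   `base`, `lower`, `upper`; defaults to
#'   [default_sensitivity_ranges()] for the configured scenario.
#' @return data.frame with columns `parameter`, `bound`, `value`,
#'   `avoided_rti_days`, `societal_savings_usd`; the first row is the
#'   base case.
#' @export
one_way_sensitivity <- function(config = default_run_config(),
                                ranges = default_sensitivity_ranges(config$scenario$name)) {
  run_one <- function(cfg) {
    run <- run_burden_model(cfg)
    ot <- run$outcomes
    c(avoided_rti_days = -ot$difference[ot$outcome == "rti_days"],
      societal_savings_usd = run$costs$national["savings", "societal"])
  }
  base_out <- run_one(config)
  rows <- list(data.frame(parameter = "base_case", bound = "base", value = NA_real_,
                          avoided_rti_days = base_out[[1]],
                          societal_savings_usd = base_out[[2]]))
  for (i in seq_len(nrow(ranges))) {
    for (bound in c("lower", "upper")) {
      val <- ranges[[bound]][i]
      cfg <- set_config_path(config, ranges$parameter[i], val)
      out <- run_one(cfg)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = ranges$parameter[i], bound = bound, value = val,
        avoided_rti_days = out[[1]], societal_savings_usd = out[[2]]
      )
    }
  }
  do.call(rbind, rows)
}

#' Convergence test over sample rates and replicate seeds
#'
#' Runs the configured scenario at each sample rate with `replicates`
#' distinct seeds and reports the mean and coefficient of variation (CV, %)
#' of the headline outcomes across replicates. The model is flagged as
#' converged when the CV of the RTI-day percentage reduction at the largest
#' sample rate is below `cv_threshold`.
#'
#' @param config A run configuration.
#' @param sample_rates Numeric vector of at least two sampling fractions.
#' @param replicates Number of replicate seeds per rate (>= 3).
#' @param cv_threshold Convergence CV threshold in percent (default 2).
#' @return List with `table` (rate, n_persons, outcome, mean, cv_pct) and
#'   `converged` (logical).
#' @export
convergence_test <- function(config, sample_rates, replicates = 3,
                             cv_threshold = 2) {
  if (length(sample_rates) < 2) {
    stop("convergence_test: need at least two sample rates", call. = FALSE)
  }
  if (replicates < 3) {
    stop("convergence_test: need at least three replicates per rate", call. = FALSE)
  }
  outcomes <- c("pct_day_reduction", "avoided_rti_days", "pct_abx_reduction")
  rows <- list()
  for (rate in sort(sample_rates)) {
    vals <- matrix(NA_real_, replicates, length(outcomes),
                   dimnames = list(NULL, outcomes))
    for (rep_i in seq_len(replicates)) {
      cfg <- config
      cfg$population$sample_rate <- rate
      cfg$seed <- config$seed + rep_i - 1L
      run <- run_burden_model(cfg)
      ot <- run$outcomes
      vals[rep_i, ] <- c(
        -ot$pct_difference[ot$outcome == "rti_days"],
        -ot$difference[ot$outcome == "rti_days"],
        -ot$pct_difference[ot$outcome == "antibiotic_courses"]
      )
    }
    n_persons <- round(config$population$reference_total * rate)
    for (oc in outcomes) {
      m <- mean(vals[, oc])
      rows[[length(rows) + 1]] <- data.frame(
        sample_rate = rate, n_persons = n_persons, outcome = oc,
        mean = m, cv_pct = if (m == 0) NA_real_ else 100 * sd(vals[, oc]) / abs(m)
      )
    }
  }
  tab <- do.call(rbind, rows)
  top <- tab[tab$sample_rate == max(tab$sample_rate) &
               tab$outcome == "pct_day_reduction", ]
  structure(list(table = tab, converged = isTRUE(top$cv_pct < cv_threshold)),
            class = "convergence_report")
}
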