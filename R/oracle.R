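# Closed-form expected values for the headline relative reductions and cost
# savings. The oracle treats the two vaccination strata separately, applies
# each effect where the scenario's restriction rules say it applies, and
# deliberately ignores second-order feedback (at-risk time freed by averted
# episodes), which is below a percentage point at the model's parameter
# values.

# Per-stratum (unvaccinated, vaccinated) expectation multipliers. `pick`
# selects which effects enter: episodes ("inc"), days ("inc" x "dur"),
# courses ("inc" x "abx"). Uptake dilutes every effect per person.
stratum_multiplier <- function(spec, effects) {
  up <- spec$uptake_fraction
  dmult <- 1 - spec$duration_reduction_days / spec$base_mean_days
  one <- c(unvaccinated = 1, vaccinated = 1)
  f <- function(value, restricted) {
    m <- c(unvaccinated = value,
           vaccinated = if (restricted) 1 else value)
    m
  }
  active <- one
  if ("inc" %in% effects) {
    active <- active * f(spec$incidence_rr, spec$restrict_incidence_to_unvaccinated)
  }
  if ("dur" %in% effects) {
    active <- active * f(dmult, spec$restrict_duration_to_unvaccinated)
  }
  if ("abx" %in% effects) {
    active <- active * f(spec$antibiotic_rr, spec$restrict_antibiotic_to_unvaccinated)
  }
  # per-person expectation with uptake dilution: non-users keep multiplier 1
  (1 - up) + up * active
}

weighted_ratio <- function(spec, u_e, effects) {
  m <- stratum_multiplier(spec, effects)
  u_e * m[["unvaccinated"]] + (1 - u_e) * m[["vaccinated"]]
}

#' Expected percentage reduction in total RTI days
#'
#' Closed form: with the duration effect applied universally (YHEC) the
#' reduction is `100 * reduction/base mean`; with incidence and duration
#' effects restricted to the unvaccinated stratum (Cochrane) it is
#' `100 * (1 - ((1-u) + u * incidence_rr * duration_mult))` at unvaccinated
#' episode share `u`.
#'
#' @param spec A [scenario_spec()].
#' @param u_e Unvaccinated share of control-arm episodes (default 0.554).
#' @return Percentage reduction (positive = fewer days with probiotics).
#' @export
expected_reduction_days <- function(spec, u_e = 0.554) {
  100 * (1 - weighted_ratio(spec, u_e, c("inc", "dur")))
}

#' Expected percentage reduction in RTI episodes
#'
#' `100 * u * (1 - incidence_rr)` when the incidence effect is restricted to
#' unvaccinated persons; zero when the scenario has no incidence effect.
#'
#' @inheritParams expected_reduction_days
#' @export
expected_reduction_episodes <- function(spec, u_e = 0.554) {
  100 * (1 - weighted_ratio(spec, u_e, "inc"))
}

#' Expected percentage reduction in antibiotic courses
#'
#' Combines the episode reduction with the antibiotic rate-ratio effect per
#' stratum: YHEC gives `100 * u * (1 - antibiotic_rr)`; Cochrane
#' `100 * (1 - ((1-u) + u * incidence_rr * antibiotic_rr))`.
#'
#' @inheritParams expected_reduction_days
#' @export
expected_reduction_antibiotics <- function(spec, u_e = 0.554) {
  100 * (1 - weighted_ratio(spec, u_e, c("inc", "abx")))
}

#' Oracle inputs
#'
#' Composite quantities the closed-form savings oracle conditions on: the
#' control-arm episode total at sample scale, the unvaccinated episode
#' share, the episode shares of children (for caregiver absence; age 0–15)
#' and of the antibiotic child price band (age 0–14), the employed share of
#' adult episodes, and the cost and absenteeism parameter sets. Defaults are
#' the base-case values implied by the default cohort and the child/adult
#' incidence ratio 2.85.
#'
#' @param unvaccinated_episode_share,control_episodes Calibration anchors.
#' @param child_episode_share Share of episodes accruing to children 0–15.
#' @param child_0_14_episode_share Share billed at the child antibiotic
#'   price.
#' @param employed_episode_share Share of all episodes accruing to employed
#'   persons.
#' @param costs A [cost_params()].
#' @param absent An [absenteeism_params()].
#' @return An object of class `oracle_inputs`.
#' @export
oracle_inputs <- function(unvaccinated_episode_share = 0.554,
                          control_episodes = 24671,
                          child_episode_share = 0.4131,
                          child_0_14_episode_share = 0.3867,
                          employed_episode_share = 0.3383,
                          costs = cost_params(),
                          absent = absenteeism_params()) {
  oi <- list(
    unvaccinated_episode_share = unvaccinated_episode_share,
    control_episodes = control_episodes,
    child_episode_share = child_episode_share,
    child_0_14_episode_share = child_0_14_episode_share,
    employed_episode_share = employed_episode_share,
    costs = costs, absent = absent
  )
  if (unvaccinated_episode_share < 0 || unvaccinated_episode_share > 1 ||
      control_episodes <= 0) {
    stop("oracle_inputs: share must lie in [0,1] and episode total be > 0", call. = FALSE)
  }
  class(oi) <- "oracle_inputs"
  oi
}

#' Expected event differences and national cost savings
#'
#' Closed-form counterpart of the full pipeline. Averted episodes, RTI days,
#' antibiotic courses and missed work days follow from the stratum
#' multipliers; payer savings are averted episodes times the expected
#' per-episode payer cost without antibiotics
#' (`pcp_payer + othermed_prob * othermed_payer`) plus averted courses times
#' the age-weighted course cost; societal savings add averted copayments and
#' averted missed days valued at the daily productivity cost. National
#' figures apply the projection factor.
#'
#' @param spec A [scenario_spec()].
#' @param oi An [oracle_inputs()].
#' @return List with sample-scale `averted_episodes`, `averted_days`,
#'   `averted_courses`, `averted_missed_days`, and national-scale
#'   `payer_usd`, `societal_usd`, `payer_million_usd`,
#'   `societal_million_usd`.
#' @export
expected_savings <- function(spec, oi = oracle_inputs()) {
  u <- oi$unvaccinated_episode_share
  e0 <- oi$control_episodes
  cp <- oi$costs
  ap <- oi$absent

  averted_eps <- e0 * (1 - weighted_ratio(spec, u, "inc"))
  averted_days <- e0 * spec$base_mean_days * (1 - weighted_ratio(spec, u, c("inc", "dur")))
  averted_courses <- e0 * cp$abx_prescription_prob *
    (1 - weighted_ratio(spec, u, c("inc", "abx")))

  # two-part absence model: per-episode expected missed days by group
  miss_emp <- ap$employee_absence_prob * ap$employee_mean_days
  miss_child <- ap$child_absence_prob * ap$child_mean_days
  phi_a <- 1 - spec$absent_reduction_adult_days / ap$employee_mean_days
  phi_c <- 1 - spec$absent_reduction_child_days / ap$child_mean_days
  up <- spec$uptake_fraction
  miss0 <- oi$employed_episode_share * miss_emp + oi$child_episode_share * miss_child
  m0 <- e0 * miss0
  mp <- 0
  for (s in c("unvaccinated", "vaccinated")) {
    w <- if (s == "unvaccinated") u else 1 - u
    inc_s <- if (s == "unvaccinated" || !spec$restrict_incidence_to_unvaccinated)
      spec$incidence_rr else 1
    abs_s <- !(spec$restrict_absence_to_unvaccinated && s == "vaccinated")
    # probiotic users: episode thinning and absence scaling apply jointly;
    # non-users contribute the control expectation unchanged
    miss_user <- inc_s * (oi$employed_episode_share * miss_emp * (if (abs_s) phi_a else 1) +
                          oi$child_episode_share * miss_child * (if (abs_s) phi_c else 1))
    mp <- mp + e0 * w * ((1 - up) * miss0 + up * miss_user)
  }
  averted_missed <- m0 - mp

  course_cost <- oi$child_0_14_episode_share * cp$abx_cost_child +
    (1 - oi$child_0_14_episode_share) * cp$abx_cost_adult
  payer <- averted_eps * (cp$pcp_payer + cp$othermed_prob * cp$othermed_payer) +
    averted_courses * course_cost
  copay <- averted_eps * (cp$pcp_copay + cp$othermed_prob * cp$othermed_copay) +
    averted_courses * cp$abx_copay
  productivity <- averted_missed * cp$productivity_per_day
  pf <- cp$projection_factor

  list(
    averted_episodes = averted_eps,
    averted_days = averted_days,
    averted_courses = averted_courses,
    averted_missed_days = averted_missed,
    payer_usd = payer * pf,
    societal_usd = (payer + copay + productivity) * pf,
    payer_million_usd = payer * pf / 1e6,
    societal_million_usd = (payer + copay + productivity) * pf / 1e6
  )
}
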