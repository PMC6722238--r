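# Daily RTI onset hazard (seasonality, vaccination, risk factors), episode
# duration model, and the two-parameter incidence calibration.

#' Seasonal profile of daily onset weights
#'
#' 365 non-negative day weights summing to 1. The `"flat"` preset is uniform;
#' `"winter_peak"` is a circular von-Mises-shaped curve peaking at
#' `peak_day`, a stylized stand-in for the winter consultation wave. The
#' incidence calibration absorbs the profile shape, so headline percentage
#' reductions are insensitive to it.
#'
#' @param preset `"winter_peak"` or `"flat"`.
#' @param peak_day Day of year of the peak (default 35, early February).
#' @param concentration Non-negative peak concentration; 0 is flat.
#' @return Numeric vector of length 365, class `seasonal_profile`.
#' @export
seasonal_profile <- function(preset = c("winter_peak", "flat"),
                             peak_day = 35L, concentration = 2) {
  preset <- match.arg(preset)
  if (concentration < 0) {
    stop("seasonal_profile: concentration must be >= 0", call. = FALSE)
  }
  d <- seq_len(365)
  w <- switch(preset,
    flat = rep(1, 365),
    winter_peak = exp(concentration * cos(2 * pi * (d - peak_day) / 365))
  )
  w <- w / sum(w)
  structure(w, class = "seasonal_profile", preset = preset)
}

#' Risk-factor effect set
#'
#' Multiplicative effects of risk factors on RTI incidence and duration, and
#' the child/adult incidence ratio. Incidence rate ratios: passive smoking
#' 1.15, school/day-care attendance 1.22 (ages 1–15), shared office or
#' nursing-home residence 1.07. Duration multipliers: active smoking +16.8%,
#' passive smoking +4.5%. The child/adult incidence ratio defaults to 2.85,
#' the value implied by the children's share of avoided RTI days relative to
#' their population share.
#'
#' With `modifiers = FALSE` (the base case) the five risk-factor effects are
#' identity while the child/adult ratio is retained; the risk factors then
#' only define subgroups, matching the study design in which they enter
#' subgroup analyses but not the base case.
#'
#' @param passive_smoke_incidence_rr,school_incidence_rr,shared_office_incidence_rr
#'   Incidence rate ratios (> 0).
#' @param active_smoke_duration_mult,passive_smoke_duration_mult Duration
#'   multipliers (> 0).
#' @param child_adult_incidence_ratio Ratio of child to adult baseline
#'   incidence (> 0).
#' @param modifiers If `FALSE`, set the five risk-factor effects to 1.
#' @return An object of class `risk_effects`.
#' @export
risk_effects <- function(passive_smoke_incidence_rr = 1.15,
                         school_incidence_rr = 1.22,
                         shared_office_incidence_rr = 1.07,
                         active_smoke_duration_mult = 1.168,
                         passive_smoke_duration_mult = 1.045,
                         child_adult_incidence_ratio = 2.85,
                         modifiers = TRUE) {
  if (!modifiers) {
    passive_smoke_incidence_rr <- 1
    school_incidence_rr <- 1
    shared_office_incidence_rr <- 1
    active_smoke_duration_mult <- 1
    passive_smoke_duration_mult <- 1
  }
  re <- list(
    passive_smoke_incidence_rr = passive_smoke_incidence_rr,
    school_incidence_rr = school_incidence_rr,
    shared_office_incidence_rr = shared_office_incidence_rr,
    active_smoke_duration_mult = active_smoke_duration_mult,
    passive_smoke_duration_mult = passive_smoke_duration_mult,
    child_adult_incidence_ratio = child_adult_incidence_ratio
  )
  if (any(unlist(re) <= 0)) {
    stop("risk_effects: all ratios must be > 0", call. = FALSE)
  }
  class(re) <- "risk_effects"
  re
}

#' Incidence model
#'
#' The daily RTI onset hazard model: a seasonal profile, a base daily hazard
#' (adult, unvaccinated, no risk factors), a vaccinated/unvaccinated rate
#' ratio, and multiplicative risk-factor effects. `base_daily_hazard` and
#' `vaccinated_rate_ratio` are normally left `NA` and solved by
#' [calibrate_incidence()] against the two calibration targets: the seasonal
#' no-probiotic episode count (24,671 per 329,256 persons) and the
#' unvaccinated share of episodes (0.554).
#'
#' @param profile A [seasonal_profile()].
#' @param base_daily_hazard Baseline daily hazard; `NA` until calibrated.
#' @param vaccinated_rate_ratio Vaccinated vs unvaccinated hazard ratio in
#'   (0, 1]; `NA` until calibrated (calibrates to ~0.934).
#' @param risk A [risk_effects()].
#' @param calibration_target_episodes Target control-arm episode count at
#'   `reference_cohort_size` persons.
#' @param target_unvaccinated_episode_share Target share of episodes accruing
#'   to unvaccinated persons.
#' @param reference_cohort_size Cohort size at which the episode target is
#'   stated; the target is rescaled proportionally to the simulated cohort.
#' @return An object of class `incidence_model`.
#' @export
incidence_model <- function(profile = seasonal_profile(),
                            base_daily_hazard = NA_real_,
                            vaccinated_rate_ratio = NA_real_,
                            risk = risk_effects(modifiers = FALSE),
                            calibration_target_episodes = 24671,
                            target_unvaccinated_episode_share = 0.554,
                            reference_cohort_size = 329256) {
  stopifnot(inherits(profile, "seasonal_profile"), inherits(risk, "risk_effects"))
  m <- list(
    profile = profile,
    base_daily_hazard = base_daily_hazard,
    vaccinated_rate_ratio = vaccinated_rate_ratio,
    risk = risk,
    calibration_target_episodes = calibration_target_episodes,
    target_unvaccinated_episode_share = target_unvaccinated_episode_share,
    reference_cohort_size = reference_cohort_size
  )
  class(m) <- "incidence_model"
  m
}

is_calibrated <- function(model) {
  is.finite(model$base_daily_hazard) && is.finite(model$vaccinated_rate_ratio)
}

# Per-person hazard multiplier, excluding (exclude_vacc) or including the
# vaccination ratio. Vectorized over the population table.
person_hazard_multiplier <- function(pop, risk, vaccinated_rate_ratio = 1,
                                     exclude_vacc = FALSE) {
  mult <- rep(1, nrow(pop))
  mult[pop$is_child] <- mult[pop$is_child] * risk$child_adult_incidence_ratio
  mult[pop$passive_smoker] <- mult[pop$passive_smoker] * risk$passive_smoke_incidence_rr
  mult[pop$in_school] <- mult[pop$in_school] * risk$school_incidence_rr
  office <- (pop$employed & pop$office_shared) | pop$nursing_home
  mult[office] <- mult[office] * risk$shared_office_incidence_rr
  if (!exclude_vacc) {
    mult[pop$vaccinated] <- mult[pop$vaccinated] * vaccinated_rate_ratio
  }
  mult
}

#' Effective daily onset hazard for given persons and day
#'
#' The hazard factorizes multiplicatively:
#' `base_daily_hazard * 365 * profile[day]`, times the child/adult incidence
#' ratio for children, the vaccinated rate ratio for vaccinated persons, and
#' the risk-factor incidence rate ratios where the person's flags apply. The
#' result is clipped to `[0, 1)`; the engine converts hazards to daily onset
#' probabilities via `1 - exp(-hazard)`.
#'
#' @param person One or more rows of a `person_table`.
#' @param day Day of year, 1–365.
#' @param model A calibrated [incidence_model()].
#' @return Numeric hazard, one value per person row.
#' @export
effective_daily_hazard <- function(person, day, model) {
  if (length(day) != 1 || !is.finite(day) || day < 1 || day > 365) {
    stop("effective_daily_hazard: day must be a single value in 1..365", call. = FALSE)
  }
  if (!is_calibrated(model)) {
    stop("effective_daily_hazard: model is not calibrated", call. = FALSE)
  }
  mult <- person_hazard_multiplier(person, model$risk, model$vaccinated_rate_ratio)
  h <- model$base_daily_hazard * 365 * model$profile[as.integer(day)] * mult
  pmin(pmax(h, 0), 1 - 1e-12)
}

#' Episode duration model
#'
#' Episode durations are continuous days drawn from a gamma distribution
#' rescaled to the person-level mean. `dispersion` is the coefficient of
#' variation (sd/mean); the gamma shape is `1/dispersion^2`. A dispersion of
#' zero degenerates to the mean. Sampled durations are floored at
#' `minimum_days`.
#'
#' @param base_mean_days Mean episode duration in days for a person with no
#'   duration-modifying factors (7.4 in the YHEC scenario, 8.82 Cochrane).
#' @param dispersion Coefficient of variation of the duration draw
#'   (default 0.45).
#' @param minimum_days Floor on sampled durations (default 0.5).
#' @return An object of class `duration_model`.
#' @export
duration_model <- function(base_mean_days = 7.4, dispersion = 0.45,
                           minimum_days = 0.5) {
  if (base_mean_days <= 0) stop("duration_model: base_mean_days must be > 0", call. = FALSE)
  if (dispersion < 0) stop("duration_model: dispersion must be >= 0", call. = FALSE)
  if (minimum_days < 0) stop("duration_model: minimum_days must be >= 0", call. = FALSE)
  dm <- list(base_mean_days = base_mean_days, dispersion = dispersion,
             minimum_days = minimum_days)
  class(dm) <- "duration_model"
  dm
}

#' Person-level mean episode duration
#'
#' `base_mean_days` times the active- or passive-smoking duration multiplier
#' where the person's flags apply, times a scenario multiplier (the probiotic
#' duration effect, `1 - reduction/base mean`).
#'
#' @param person One or more rows of a `person_table`.
#' @param dm A [duration_model()].
#' @param risk A [risk_effects()].
#' @param scenario_multiplier Multiplier in (0, 1]; 1 for the control arm.
#' @return Numeric vector of mean durations in days.
#' @export
mean_duration <- function(person, dm, risk, scenario_multiplier = 1) {
  if (any(scenario_multiplier <= 0) || any(scenario_multiplier > 1)) {
    stop("mean_duration: scenario_multiplier must lie in (0, 1]", call. = FALSE)
  }
  m <- rep(dm$base_mean_days, nrow(person))
  m[person$active_smoker] <- m[person$active_smoker] * risk$active_smoke_duration_mult
  m[person$passive_smoker] <- m[person$passive_smoker] * risk$passive_smoke_duration_mult
  m * scenario_multiplier
}

#' Sample an episode duration from its mean and a uniform draw
#'
#' Inverse-transform draw from the gamma family rescaled to `mean`; strictly
#' increasing in `draw`, which is what allows common-random-numbers pairing
#' across arms, and mean-exact up to the `minimum_days` floor. For two means
#' `m` and `c*m` and the same draw, the (unfloored) durations are in exact
#' ratio `c`.
#'
#' @param mean Target mean duration (days), vectorized.
#' @param dm A [duration_model()].
#' @param draw Uniform(0,1) draw(s), same length as `mean` or length 1.
#' @return Durations in days, floored at `dm$minimum_days`.
#' @export
sample_duration <- function(mean, dm, draw) {
  if (any(mean <= 0)) stop("sample_duration: mean must be > 0", call. = FALSE)
  if (dm$dispersion < 1e-8) {
    d <- rep_len(mean, max(length(mean), length(draw)))
  } else {
    shape <- 1 / dm$dispersion^2
    d <- qgamma(draw, shape = shape, scale = mean / shape)
  }
  pmax(d, dm$minimum_days)
}

# Distribution of the number of whole days an episode suppresses the at-risk
# state (ceil of the gamma duration), used by the deterministic calibration.
ceil_duration_dist <- function(mean, dm) {
  if (dm$dispersion < 1e-8) {
    j <- max(1, ceiling(mean))
    return(setNames(1, j))
  }
  shape <- 1 / dm$dispersion^2
  scale <- mean / shape
  jmax <- max(2, ceiling(qgamma(1 - 1e-10, shape = shape, scale = scale)))
  p <- diff(pgamma(0:jmax, shape = shape, scale = scale))
  p[jmax] <- p[jmax] + (1 - sum(p))  # fold residual tail mass
  setNames(p, seq_len(jmax))
}

# Deterministic per-pattern expectation of seasonal episode count: a renewal
# recursion over 365 days tracking the at-risk probability, with onsets
# returning to risk after ceil(duration) days.
expected_episodes_pattern <- function(lam_day, ceil_dist, horizon = 365) {
  p <- -expm1(-pmin(lam_day, 0.999999))
  j <- as.integer(names(ceil_dist))
  A <- 1
  ret <- numeric(horizon + max(j) + 1)
  total <- 0
  for (d in seq_len(horizon)) {
    o <- A * p[d]
    total <- total + o
    ret[d + j] <- ret[d + j] + o * ceil_dist
    A <- A - o + ret[d + 1]
  }
  total
}

#' Calibrate the incidence model to its episode and vaccination targets
#'
#' Two-parameter deterministic calibration. The base daily hazard is scaled
#' so the expected control-arm episode count over the horizon — computed by a
#' per-covariate-pattern renewal recursion that accounts for at-risk time
#' lost to ongoing episodes — equals `calibration_target_episodes` rescaled
#' to the cohort size; the vaccinated rate ratio is solved so the expected
#' unvaccinated share of episodes equals `target_unvaccinated_episode_share`.
#' A fixed-point iteration alternates the two updates and converges when both
#' targets are met within `tol` (relative).
#'
#' @param pop A `person_table`.
#' @param model An [incidence_model()] with targets set.
#' @param dm A [duration_model()] (durations determine time lost to
#'   ongoing episodes).
#' @param horizon Number of daily cycles (default 365).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap.
#' @return The calibrated `incidence_model`, with attribute `calibration`
#'   (a list with expected episodes, share, residuals, iterations).
#' @export
calibrate_incidence <- function(pop, model, dm, horizon = 365,
                                tol = 1e-6, max_iter = 60) {
  stopifnot(inherits(model, "incidence_model"), inherits(dm, "duration_model"))
  n <- nrow(pop)
  target_eps <- model$calibration_target_episodes * n / model$reference_cohort_size
  target_share <- model$target_unvaccinated_episode_share
  if (target_eps <= 0) stop("calibrate_incidence: episode target must be > 0", call. = FALSE)

  mult0 <- person_hazard_multiplier(pop, model$risk, exclude_vacc = TRUE)
  mdur <- mean_duration(pop, dm, model$risk, 1)
  pat <- data.table(mult0 = mult0, vacc = pop$vaccinated, m = mdur)
  pat <- pat[, .(n = .N), by = .(mult0, vacc, m)]
  dists <- lapply(unique(pat$m), function(m) ceil_duration_dist(m, dm))
  names(dists) <- as.character(unique(pat$m))
  prof <- as.numeric(model$profile)[seq_len(min(horizon, 365))]
  if (horizon > 365) prof <- rep_len(prof, horizon)

  # starting values: ignore suppression; closed-form vaccination ratio
  b <- target_eps / (sum(pat$n * pat$mult0) * 365 * sum(prof))
  vshare <- mean(pop$vaccinated)
  # a single-stratum cohort pins the episode share; only the hazard is solved
  single_stratum <- vshare == 0 || vshare == 1 || target_share %in% c(0, 1)
  r <- if (single_stratum) 1 else {
    min(max(((1 - vshare) * (1 - target_share)) / (vshare * target_share), 1e-6), 1)
  }

  expectation <- function(b, r) {
    e <- numeric(nrow(pat))
    for (i in seq_len(nrow(pat))) {
      lam <- b * 365 * prof * pat$mult0[i] * (if (pat$vacc[i]) r else 1)
      e[i] <- pat$n[i] * expected_episodes_pattern(lam, dists[[as.character(pat$m[i])]], horizon)
    }
    list(total = sum(e), unvacc = sum(e[!pat$vacc]))
  }

  iter <- 0
  repeat {
    iter <- iter + 1
    ex <- expectation(b, r)
    share <- ex$unvacc / ex$total
    res_eps <- ex$total / target_eps - 1
    res_share <- if (single_stratum) 0 else share - target_share
    if (abs(res_eps) < tol && abs(res_share) < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "calibrate_incidence: no convergence after %d iterations (episode residual %.3g, share residual %.3g)",
        iter, res_eps, res_share), call. = FALSE)
    }
    b <- b * target_eps / ex$total
    if (!single_stratum) {
      r <- r * (share / (1 - share)) / (target_share / (1 - target_share))
      r <- min(max(r, 1e-9), 1)
    }
  }

  model$base_daily_hazard <- b
  model$vaccinated_rate_ratio <- r
  attr(model, "calibration") <- list(
    expected_episodes = ex$total, target_episodes = target_eps,
    unvaccinated_share = share, target_share = target_share,
    episode_residual = res_eps, share_residual = res_share,
    iterations = iter
  )
  model
}
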