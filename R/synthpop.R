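# Synthetic cohort generation: a 1/1,000-scale US-like population with the
# subgroup prevalences the burden model conditions on.

#' Default age-band distribution of the synthetic cohort
#'
#' Eight coarse age bands with probabilities chosen so the expected share of
#' children aged 0–15 is 19.81%, the share the model population is built to
#' carry. Ages are drawn uniformly (integer years) within a band.
#'
#' @return A data.frame with columns `lower`, `upper` (inclusive integer age
#'   bounds) and `prob` (band probability; sums to 1).
#' @export
default_age_bands <- function() {
  data.frame(
    lower = c(0L, 5L, 10L, 16L, 25L, 45L, 65L, 75L),
    upper = c(4L, 9L, 15L, 24L, 44L, 64L, 74L, 94L),
    prob  = c(0.0605, 0.0615, 0.0761, 0.1205, 0.2620, 0.2595, 0.0950, 0.0649)
  )
}

#' Population configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the model
#' population: a 1/1,000 sample of 329,256,000 persons (329,256 individuals)
#' with 53.70% unvaccinated, 19.81% children aged 0–15, 12.50% active
#' smokers, 26.59% passive smokers and 53.19% of individuals in a shared
#' daily indoor environment (school, shared office, or nursing home).
#'
#' @param sample_rate Sampling fraction of the reference population.
#' @param reference_total Reference population size the sample is drawn from.
#' @param age_bands Age-band distribution, see [default_age_bands()].
#' @param female_fraction Probability of being female (demographic fidelity
#'   only; gender has no effect on hazards or costs).
#' @param unvaccinated_prob Probability of being unvaccinated against
#'   influenza (0.5370).
#' @param active_smoker_share Target cohort-level share of active smokers
#'   (0.1250). Apportioned over persons aged `active_smoker_min_age` and
#'   older with a single rate so the cohort share matches.
#' @param active_smoker_min_age Youngest age eligible for active smoking
#'   (middle/high-school ages and adults; default 12).
#' @param passive_smoker_prob Target cohort-level share of passive smokers
#'   (0.2659); mutually exclusive with active smoking.
#' @param employment_rate_16plus Employment probability among persons aged
#'   16+ (default 0.58, which reproduces the baseline total of missed work
#'   days).
#' @param school_enrollment_prob_1_15 School/day-care enrollment probability
#'   for ages 1 to `child_age_cutoff`.
#' @param nursing_home_prob_65plus Probability of nursing-home residence for
#'   ages 65+; residents are not employed.
#' @param shared_office_prob_employed Probability that an employed person
#'   works in a shared office (default 0.758, calibrated so the composite
#'   shared-indoor share is 53.19%).
#' @param child_age_cutoff Oldest age counted as a child (default 15).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return An object of class `population_config`.
#' @export
population_config <- function(sample_rate = 1 / 1000,
                              reference_total = 329256000,
                              age_bands = default_age_bands(),
                              female_fraction = 0.508,
                              unvaccinated_prob = 0.5370,
                              active_smoker_share = 0.1250,
                              active_smoker_min_age = 12L,
                              passive_smoker_prob = 0.2659,
                              employment_rate_16plus = 0.58,
                              school_enrollment_prob_1_15 = 0.95,
                              nursing_home_prob_65plus = 0.03,
                              shared_office_prob_employed = 0.758,
                              child_age_cutoff = 15L,
                              seed = 1L) {
  cfg <- list(
    sample_rate = sample_rate, reference_total = reference_total,
    age_bands = age_bands, female_fraction = female_fraction,
    unvaccinated_prob = unvaccinated_prob,
    active_smoker_share = active_smoker_share,
    active_smoker_min_age = as.integer(active_smoker_min_age),
    passive_smoker_prob = passive_smoker_prob,
    employment_rate_16plus = employment_rate_16plus,
    school_enrollment_prob_1_15 = school_enrollment_prob_1_15,
    nursing_home_prob_65plus = nursing_home_prob_65plus,
    shared_office_prob_employed = shared_office_prob_employed,
    child_age_cutoff = as.integer(child_age_cutoff),
    seed = as.integer(seed)
  )
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  probs <- c(
    cfg$female_fraction, cfg$unvaccinated_prob, cfg$active_smoker_share,
    cfg$passive_smoker_prob, cfg$employment_rate_16plus,
    cfg$school_enrollment_prob_1_15, cfg$nursing_home_prob_65plus,
    cfg$shared_office_prob_employed
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("population_config: all probabilities must lie in [0, 1]", call. = FALSE)
  }
  ab <- cfg$age_bands
  if (!all(c("lower", "upper", "prob") %in% names(ab))) {
    stop("population_config: age_bands needs columns lower/upper/prob", call. = FALSE)
  }
  if (any(ab$prob < 0) || abs(sum(ab$prob) - 1) > 1e-9) {
    stop("population_config: age-band probabilities must be >= 0 and sum to 1", call. = FALSE)
  }
  if (any(ab$upper < ab$lower)) {
    stop("population_config: age band upper < lower", call. = FALSE)
  }
  n <- expected_cohort_size(cfg)
  if (!is.finite(n) || n <= 0) {
    stop("population_config: expected cohort size is zero; increase sample_rate",
         call. = FALSE)
  }
  invisible(cfg)
}

expected_cohort_size <- function(cfg) {
  round(cfg$reference_total * cfg$sample_rate)
}

# Probability that a drawn age falls in [lo, hi] under the band distribution
# (integer ages uniform within each band).
age_range_prob <- function(age_bands, lo, hi) {
  width <- age_bands$upper - age_bands$lower + 1L
  inside <- pmax(0L, pmin(age_bands$upper, hi) - pmax(age_bands$lower, lo) + 1L)
  sum(age_bands$prob * inside / width)
}

#' Generate the synthetic study cohort
#'
#' Draws one person per row with demographic, vaccination and risk-factor
#' attributes. Active and passive smoking are mutually exclusive; school
#' enrollment is confined to ages 1 to the child cutoff; employment to ages
#' 16+ outside nursing homes. `shared_indoor` flags a daily shared indoor
#' environment: in school, employed in a shared office, or a nursing-home
#' resident.
#'
#' @param config A [population_config()].
#' @return A `data.table` of class `person_table`, one row per person, with
#'   columns `person_id`, `age`, `is_female`, `vaccinated`, `active_smoker`,
#'   `passive_smoker`, `in_school`, `employed`, `office_shared`,
#'   `nursing_home`, `shared_indoor`, `is_child`.
#' @examples
#' pop <- generate_population(population_config(sample_rate = 1 / 10000))
#' summarize_population(pop)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  validate_population_config(config)
  n <- expected_cohort_size(config)
  ab <- config$age_bands

  pop <- withr::with_seed(config$seed, {
    band <- sample.int(nrow(ab), n, replace = TRUE, prob = ab$prob)
    width <- ab$upper - ab$lower + 1L
    age <- ab$lower[band] + floor(runif(n) * width[band])
    age <- as.integer(pmin(age, ab$upper[band]))  # guard runif == 1 edge

    is_female <- runif(n) < config$female_fraction
    vaccinated <- runif(n) >= config$unvaccinated_prob
    is_child <- age <= config$child_age_cutoff

    # single apportionment rate over smoking-eligible ages so the cohort-level
    # active-smoker share hits its target
    p_elig <- age_range_prob(ab, config$active_smoker_min_age, max(ab$upper))
    rate_active <- if (p_elig > 0) min(1, config$active_smoker_share / p_elig) else 0
    active_smoker <- age >= config$active_smoker_min_age & runif(n) < rate_active
    # passive smoking drawn among non-active persons; conditional rate chosen
    # so the cohort share matches the target despite the exclusivity rule
    p_cond <- min(1, config$passive_smoker_prob / max(1e-12, 1 - config$active_smoker_share))
    passive_smoker <- !active_smoker & runif(n) < p_cond

    in_school <- age >= 1L & age <= config$child_age_cutoff &
      runif(n) < config$school_enrollment_prob_1_15
    nursing_home <- age >= 65L & runif(n) < config$nursing_home_prob_65plus
    employed <- age >= 16L & !nursing_home & runif(n) < config$employment_rate_16plus
    office_shared <- employed & runif(n) < config$shared_office_prob_employed

    data.table(
      person_id = seq_len(n), age = age, is_female = is_female,
      vaccinated = vaccinated, active_smoker = active_smoker,
      passive_smoker = passive_smoker, in_school = in_school,
      employed = employed, office_shared = office_shared,
      nursing_home = nursing_home,
      shared_indoor = in_school | office_shared | nursing_home,
      is_child = is_child
    )
  })
  setattr(pop, "class", c("person_table", class(pop)))
  pop
}

#' Summarize cohort subgroup prevalences
#'
#' Cohort size and the subgroup shares the model reports on: children,
#' active/passive smokers, shared indoor environment, unvaccinated,
#' employed and female.
#'
#' @param pop A `person_table` from [generate_population()].
#' @return A data.frame with one row per subgroup: `n` and `pct` (0–100).
#' @export
summarize_population <- function(pop) {
  if (!is.data.frame(pop) || nrow(pop) == 0) {
    stop("summarize_population: population table is empty", call. = FALSE)
  }
  n <- nrow(pop)
  groups <- c(
    children = mean(pop$is_child),
    active_smokers = mean(pop$active_smoker),
    passive_smokers = mean(pop$passive_smoker),
    shared_indoor = mean(pop$shared_indoor),
    unvaccinated = mean(!pop$vaccinated),
    employed = mean(pop$employed),
    female = mean(pop$is_female)
  )
  out <- data.frame(
    subgroup = names(groups),
    n = as.integer(round(groups * n)),
    pct = 100 * unname(groups)
  )
  attr(out, "cohort_size") <- n
  out
}
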