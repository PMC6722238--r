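# Costing: per-episode payer/copayment/productivity costs, arm totals, and
# the x1,000 national projection.

#' Cost and resource-use parameters
#'
#' Unit costs and resource-use probabilities per RTI episode. Every episode
#' carries one primary-care (PCP) consultation (payer 74.16 USD, copayment
#' 25 USD). Antibiotics are prescribed in 29% of episodes, costed by age
#' (2.95 USD for ages 0–14, 3.54 USD for 15+; no copayment). Other
#' prescribed medication occurs in 56.62% of episodes (payer 26.59 USD,
#' copayment 11 USD). Productivity loss is valued at 217.92 USD per missed
#' work day. Sample-scale totals are projected to the national scale with
#' `projection_factor` (1,000 for a 1/1,000 sample). An alternative
#' single-price antibiotic preset (amoxicillin, 6.49 USD for all ages) can
#' be set via `abx_cost_child = abx_cost_adult = 6.49`.
#'
#' @param pcp_payer,pcp_copay PCP consultation cost split (USD).
#' @param abx_prescription_prob Probability of an antibiotic course per
#'   episode (control arm).
#' @param abx_cost_child,abx_cost_adult Antibiotic course cost (USD) for
#'   ages 0–`abx_child_age_max` and older.
#' @param abx_child_age_max Oldest age billed at the child antibiotic price
#'   (default 14).
#' @param abx_copay Antibiotic copayment (USD).
#' @param othermed_prob Probability of other prescribed medication.
#' @param othermed_payer,othermed_copay Other-medication cost split (USD).
#' @param productivity_per_day Cost of one missed work day (USD).
#' @param projection_factor Sample-to-national multiplier.
#' @return An object of class `cost_params`; the derived `pcp_total` equals
#'   `pcp_payer + pcp_copay` (99.16 USD at defaults).
#' @export
cost_params <- function(pcp_payer = 74.16, pcp_copay = 25,
                        abx_prescription_prob = 0.29,
                        abx_cost_child = 2.95, abx_cost_adult = 3.54,
                        abx_child_age_max = 14L, abx_copay = 0,
                        othermed_prob = 0.5662,
                        othermed_payer = 26.59, othermed_copay = 11,
                        productivity_per_day = 217.92,
                        projection_factor = 1000) {
  cp <- list(
    pcp_payer = pcp_payer, pcp_copay = pcp_copay,
    pcp_total = pcp_payer + pcp_copay,
    abx_prescription_prob = abx_prescription_prob,
    abx_cost_child = abx_cost_child, abx_cost_adult = abx_cost_adult,
    abx_child_age_max = as.integer(abx_child_age_max), abx_copay = abx_copay,
    othermed_prob = othermed_prob,
    othermed_payer = othermed_payer, othermed_copay = othermed_copay,
    productivity_per_day = productivity_per_day,
    projection_factor = projection_factor
  )
  costs <- c(pcp_payer, pcp_copay, abx_cost_child, abx_cost_adult, abx_copay,
             othermed_payer, othermed_copay, productivity_per_day)
  if (any(costs < 0)) stop("cost_params: costs must be >= 0", call. = FALSE)
  if (abx_prescription_prob < 0 || abx_prescription_prob > 1 ||
      othermed_prob < 0 || othermed_prob > 1) {
    stop("cost_params: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (projection_factor <= 0) stop("cost_params: projection_factor must be > 0", call. = FALSE)
  class(cp) <- "cost_params"
  cp
}

#' Per-episode cost breakdown
#'
#' Payer cost: PCP fee, plus other-medication payer cost when used, plus the
#' age-specific antibiotic course cost when prescribed. Copayment: PCP
#' copayment plus other-medication copayment when used (plus any antibiotic
#' copayment). Productivity: missed days times the daily productivity value.
#'
#' @param rec One or more episode rows (needs `had_antibiotic`,
#'   `had_other_medication`, `missed_days`).
#' @param cp A [cost_params()].
#' @param person_age Age in years, recycled along `rec`; defaults to the
#'   ledger's `age` column.
#' @return data.frame with columns `payer`, `copay`, `productivity` (USD).
#' @export
cost_episode <- function(rec, cp, person_age = rec$age) {
  child <- person_age <= cp$abx_child_age_max
  abx_cost <- ifelse(child, cp$abx_cost_child, cp$abx_cost_adult)
  payer <- cp$pcp_payer +
    cp$othermed_payer * rec$had_other_medication +
    abx_cost * rec$had_antibiotic
  copay <- cp$pcp_copay +
    cp$othermed_copay * rec$had_other_medication +
    cp$abx_copay * rec$had_antibiotic
  productivity <- rec$missed_days * cp$productivity_per_day
  data.frame(payer = payer, copay = copay, productivity = productivity)
}

#' Aggregate ledger costs by arm, with savings and national projection
#'
#' Sums per-episode payer, copayment and productivity costs by arm; the
#' societal total is exactly their sum. Savings are control minus probiotic.
#' National totals are exactly the sample totals times the projection
#' factor.
#'
#' @param ledger An `episode_ledger`.
#' @param cp A [cost_params()].
#' @return An object of class `cost_summary`: list with `sample` and
#'   `national` data.frames (rows probiotic/control/savings; columns payer,
#'   copay, productivity, societal) and `projection_factor`.
#' @export
aggregate_costs <- function(ledger, cp = cost_params()) {
  stopifnot(inherits(ledger, "episode_ledger"))
  eps <- ledger$episodes
  comp <- c("payer", "copay", "productivity")
  totals <- matrix(0, nrow = 2, ncol = 3,
                   dimnames = list(c("probiotic", "control"), comp))
  if (nrow(eps) > 0) {
    cb <- cost_episode(eps, cp)
    for (a in rownames(totals)) {
      rows <- eps$arm == a
      totals[a, ] <- colSums(cb[rows, , drop = FALSE])
    }
  }
  sample <- as.data.frame(rbind(totals, savings = totals["control", ] - totals["probiotic", ]))
  sample$societal <- sample$payer + sample$copay + sample$productivity
  national <- sample * cp$projection_factor
  out <- list(sample = sample, national = national,
              projection_factor = cp$projection_factor)
  class(out) <- "cost_summary"
  out
}

#' @export
print.cost_summary <- function(x, ...) {
  cat("<cost_summary> sample-scale totals (USD):\n")
  print(round(x$sample, 2))
  cat(sprintf("national savings (x%g): payer %.3g USD, societal %.3g USD\n",
              x$projection_factor,
              x$national["savings", "payer"], x$national["savings", "societal"]))
  invisible(x)
}
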