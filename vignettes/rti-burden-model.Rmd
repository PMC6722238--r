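---
title: "Modeling influenza-like RTI burden and the impact of generalized probiotic intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling influenza-like RTI burden and the impact of generalized probiotic intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rtisim` is an individual-level state-transition microsimulation of
influenza-like respiratory tract infection (RTI) over one influenza season.
Each simulated person occupies one of two health states, *at risk* and
*ongoing RTI*, and is evaluated daily over a 365-day horizon. On each day an
at-risk person moves to the RTI state with probability
$p_i(d) = 1 - \exp\{-\lambda_i(d)\}$, where the hazard factorizes
multiplicatively:

$$\lambda_i(d) = \lambda_0 \cdot 365\, w_d \cdot
  \rho_{\text{child}}^{[i\ \text{child}]} \cdot
  r_{\text{vacc}}^{[i\ \text{vaccinated}]} \cdot
  \prod_k RR_k^{[i \in k]}$$

with $w_d$ a seasonal day-weight profile (summing to 1), $\rho_{\text{child}}$
the child/adult incidence ratio, $r_{\text{vacc}}$ the vaccinated/unvaccinated
rate ratio, and $RR_k$ optional risk-factor rate ratios. An episode removes
the person from the at-risk state for a continuous gamma-distributed duration;
recovery returns the person to risk, so re-infection within the season is
possible. Every episode carries exactly one primary-care consultation, an
antibiotic course with probability 0.29, other prescribed medication with
probability 0.5662, and a two-part work-absence outcome. Onsets are exogenous:
there is no person-to-person transmission, matching the consultation-rate
interpretation of the incidence data.

Two published meta-analytic probiotic effect sets are implemented as
scenarios:

* **YHEC** — mean episode duration shortened by 0.77 days on a 7.4-day mean
  (multiplier $1 - 0.77/7.4$), applied to all probiotic users; antibiotic
  prescription rate ratio 0.65, applied to unvaccinated users only; no
  incidence effect.
* **Cochrane** — incidence rate ratio 0.70, duration reduction 1.89 days on
  an 8.82-day mean, and antibiotic rate ratio 0.65, all restricted to
  unvaccinated users because the underlying meta-analysis covered
  unvaccinated people.

Work-absence effects come from the standardized mean difference −0.17
converted to days with the outcome standard deviations (0.17 × 5.1 = 0.87
days for employees, 0.17 × 1.5 = 0.26 days for children's caregivers) and are
applied to the conditional mean of the two-part absence model in both
scenarios, for vaccinated and unvaccinated users alike — the absence effect is
sourced from the YHEC meta-analysis, so the Cochrane scenario's
vaccination restriction does not extend to it. This is the only combination of
applicability rules consistent with all published outcome-table cells
(restricting the absence effect to unvaccinated persons would cap the
missed-day reduction near 37% instead of the published ≈60%).

## Costing

Each episode is costed from the payer perspective (PCP fee 74.16 USD,
age-specific antibiotic course 2.95/3.54 USD for ages 0–14/15+, other
medication 26.59 USD), the patient copayment (25 USD PCP, 11 USD other
medication), and productivity (217.92 USD per missed work day; children's
missed days represent caregiver work loss and are costed identically).
Societal cost is the exact sum payer + copayment + productivity. Sample-scale
totals are multiplied by exactly 1,000 to the national scale. Inpatient care,
over-the-counter medication and the price of probiotic products themselves are
out of scope. Of the two published antibiotic prices, the age-specific pair
(2.95/3.54 USD) is the base case: it is the only choice that reproduces the
published payer savings; the single amoxicillin price (6.49 USD) remains
available as a configuration preset.

## The synthetic cohort

`generate_population()` draws a 1/1,000 sample of a 329,256,000-person
reference population (329,256 individuals) with:

| attribute | default | note |
|---|---|---|
| age | 8 coarse bands, uniform integer ages within band | children 0–15 = 19.81% expected |
| female | 0.508 | demographic fidelity only; no effect on hazards or costs |
| unvaccinated | 0.5370 | independent of age (age-specific coverage is not used) |
| active smoker | 12.50% cohort-wide | single apportionment rate over ages ≥ 12 |
| passive smoker | 26.59% cohort-wide | mutually exclusive with active smoking |
| school enrollment | 0.95 of ages 1–15 | |
| employment | 0.58 of ages 16+ (non-nursing-home) | chosen so baseline missed work days total ≈ 6,973 per sample |
| shared office | 0.758 of the employed | calibrated so the composite shared-indoor share is 53.19% |
| nursing home | 0.03 of ages 65+ | residents are not employed |

The *shared indoor environment* subgroup is the union of school attendance,
shared-office employment and nursing-home residence. Only the composite
53.19% share is constrained by data; the split across its three components is
a modeling choice. Not all employed persons share an office — the published
composite share is arithmetically incompatible with counting all employees,
given the employment rate that reproduces baseline absenteeism — so office
sharing is an explicit attribute. Attributes are drawn independently given
age apart from the stated exclusivity rules; no correlation data are
published. The generator does not emulate household structure, geography, or
an age-resolved vaccination gradient, so subgroup attributions that would
hinge on such correlations (for example exact child shares of avoided days)
are validated only directionally.

## Calibration

Two parameters are solved deterministically rather than estimated
stochastically:

1. $\lambda_0$ is scaled so the *expected* control-arm episode count over the
   horizon equals 24,671 per 329,256 persons (rescaled proportionally for
   smaller cohorts). The expectation accounts for at-risk time lost to
   ongoing episodes with a per-covariate-pattern renewal recursion over the
   365 days, using the distribution of whole suppressed days
   (the ceiling of the gamma duration).
2. $r_{\text{vacc}}$ is solved so the expected unvaccinated share of episodes
   is 0.554. This target is reverse-derived from two independent published
   ratios (the episode and antibiotic reductions both equal the unvaccinated
   episode share times the within-stratum effect), and with 53.7% of the
   cohort unvaccinated it implies $r_{\text{vacc}} \approx 0.934$.

The fixed point alternates the two one-dimensional updates and converges to
relative residuals below $10^{-6}$ in a handful of iterations. Because
calibration matches the episode total whatever the seasonal profile, headline
percentage reductions are insensitive to the profile shape; the default is a
stylized winter-peaked curve (circular exponential, peak day 35,
concentration 2), with a flat preset available.

The child/adult incidence ratio defaults to 2.85, the value implied by
children contributing 41.3% of avoided RTI days from 19.81% of the
population when avoided days are proportional to episodes (as in the YHEC
scenario).

### Risk factors and the base case

The smoking and shared-indoor rate ratios (passive smoking incidence 1.15,
school 1.22, shared office/nursing home 1.07; duration +16.8% active /
+4.5% passive smoking) are fully wired into the hazard and duration models
but are **switched off in the base case**
(`epidemiology$include_risk_modifiers = FALSE`), where risk factors serve
only to define subgroups. Two published facts force this reading: the
control-arm day totals equal the episode target times the unmodified base
mean durations (182,713 ≈ 24,671 × 7.4 and 217,598 = 24,671 × 8.82 exactly),
which could not hold if smoker duration multipliers applied; and the source
analysis states the risk factors entered subgroup analyses only. Setting the
flag to `TRUE` activates all multipliers; the published light/heavy smoker
duration ratios are implemented only through their converted +16.8% summary
value. Whether nursing-home residents carry the shared-office ratio 1.07 is
unstated in the source; they do here.

## Pairing and variance reduction

Arms are compared under common random numbers. The daily state machine
generates the control arm; the probiotic arm is derived from the *same*
episode set:

* each episode is retained with probability equal to the person's incidence
  multiplier (uniform draw keyed by person × episode index),
* durations are scaled by the duration multiplier (inverse-transform gamma
  draws form a scale family, so scaling is mean-exact and monotone),
* antibiotic indicators use a shared uniform against the scaled probability,
* absence conditional means are scaled by the absence multiplier.

This episode-thinning design guarantees the pairing invariants exactly: the
probiotic arm's episodes are a subset of the control arm's; with no incidence
effect (YHEC) episode counts match exactly; under Cochrane a vaccinated
person's disease course is identical across arms record by record; a null
intervention yields exactly zero differences everywhere. It deliberately
ignores one second-order effect — an averted episode frees at-risk days in
which a new episode could have started — worth roughly 0.3% of the arm
difference at the model's parameter values, the same term the closed-form
oracle omits. The alternative (running the daily machine independently per
arm) would violate per-person monotonicity, because shorter probiotic
durations free at-risk days and can spawn extra episodes.

## Numerical choices

* **Durations** are continuous days with a gamma coefficient of variation of
  0.45 (shape ≈ 4.9) — the sources publish means only, and a moderately
  dispersed unimodal positive distribution is the standard choice; the
  dispersion is configurable and 0 degenerates to the mean. Durations are
  floored at 0.5 days; the floor binds with probability ~10⁻⁴ so
  mean-exactness is preserved to well under 0.1%.
* **Absence amounts** use a gamma matched to the published mean and SD
  (employees 1.7/5.1; children 0.5/1.5; both have shape 1/9, a heavy-tailed
  shape implied by SD = 3 × mean). This tail makes total missed days the
  noisiest headline outcome (per-seed CV ≈ 4–5%), which is why replicate
  seeds are averaged.
* **Horizon truncation**: episodes starting near day 365 contribute their
  full sampled duration; with ~7–9-day means this overstates in-horizon days
  by < 0.5% and cancels almost entirely between arms.
* **At-risk return**: after an onset on day $d$ with duration $L$, the person
  is at risk again on the first day ≥ $d + L$. The calibration recursion
  uses the matching ceiling distribution.
* **Episode-keyed draws** are pre-generated for up to 12 episodes per person
  per year; at seasonal hazards (~0.075 episodes/person/year, ~0.2 for
  children) the probability of exceeding this is negligible, and overflow
  episodes would reuse the final column rather than fail.
* **Uptake** is a per-person Bernoulli flag (draw ≤ uptake fraction); the
  "current intake" comparator uses 4.4%, composed of 1.6% supplement users
  and the 36%/64% supplement/food market split.

## Validation surface

The package validates itself along two independent routes:

* a **closed-form oracle** (`expected_reduction_*()`, `expected_savings()`)
  computes every headline reduction and saving from the scenario parameters
  and the calibration anchors; simulated headline percentages are required to
  agree within three Monte-Carlo standard errors across replicate seeds;
* **brute-force recursions written in the tests** independently reproduce
  the calibration expectation on homogeneous cohorts.

The test suite exercises the full 1/1,000 sample for the published-table
comparisons (five YHEC and three Cochrane replicates), a quarter-scale
sample (1/4,000) for the ten-seed oracle-agreement checks, and ~1/16,000
samples for engine and analysis unit tests; these sizes keep the suite's
Monte-Carlo error well inside the assertion tolerances. One-way sensitivity
sweeps reuse the base seed so that parameter effects are not confounded with
sampling noise, and convergence reporting flags a coefficient of variation
below 2% at the largest sample rate.

## Known limitations

* Exogenous incidence: no transmission dynamics, so interventions cannot
  have indirect (herd) effects.
* The incidence anchor is outpatient-consultation-based and therefore
  understates true community incidence; all results inherit that scale.
* Vaccination, employment and risk factors are drawn independently of each
  other (and of age beyond the stated eligibility rules).
* Subgroup percentage shares depend on the unpublished age-specific
  incidence curve; only directional statements are supported.
* Costs are season-total with no discounting, appropriate to the one-year
  horizon; QALYs and cost-effectiveness ratios are out of scope.

## Reproducing the headline results

```{r}
library(rtisim)
run <- run_burden_model(default_run_config("yhec"))
run$outcomes
run$costs
subgroup_attribution(run$ledger, run$population)
```

`scripts/acceptance.R` (in the source repository) wraps exactly this
pipeline over replicate seeds for both scenarios and writes the seed-averaged
event reductions and national savings as JSON.
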