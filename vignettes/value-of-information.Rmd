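---
title: "Methods: cost-effectiveness model and value-of-information analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness model and value-of-information analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipvoi)
```

## The decision problem

A randomized trial of goal-directed hemodynamic treatment (GDHT) versus
routine fluid therapy in aged hip-fracture patients is interim-analysed
after 99 patients: 15/49 complications under GDHT against 19/50 under
routine care. The Wald relative risk is 0.806 with a 95% interval from 0.465
to 1.397 — statistically inconclusive. Classical inference stops there;
value-of-information analysis instead asks what the residual uncertainty
*costs*. This package implements the full chain: interim statistics, a
probabilistic cost-effectiveness model, second-order Monte Carlo uncertainty
propagation, and the expected value of perfect information (EVPI) per
patient and for the population of future patients.

## Model structure and assumptions

**Decision tree (hospital episode, cycle 0).** Each strategy leads to one of
five mutually exclusive short-term outcomes: uncomplicated recovery,
cardiovascular complication, stroke, other complication (pneumonia, renal
failure, wound infection, deep-vein thrombosis, pulmonary embolism,
gastrointestinal bleeding, confusion), or in-hospital death. Routine-care
probabilities are a Dirichlet draw; GDHT probabilities are the same draw
with death scaled by the mortality relative risk and each complication by
the complications relative risk, uncomplicated recovery absorbing the
remainder (`gdht_probabilities()`). Each outcome carries a sampled episode
cost; the strategy adds its deterministic delivery cost. No QALYs accrue in
the tree and the episode cost is not discounted.

**Markov cohort model (cycles 1 to 5, annual).** States: well,
post-cardiovascular, post-stroke, post-other, recovered, dead. Structural
assumptions, following the source model: a patient has at most one
complication; cardiovascular and stroke states are lifelong (no recovery);
recovery is possible only from the other-complications state; death is
absorbing. Post-cardiovascular mortality follows the deterministic schedule
0.107 / 0.058 / 0.056 for years 1–3; only three years are published, so the
year-3 value is carried forward for cycles 4–5 (conservative and monotone).
Post-stroke mortality is 0.15 in year 1; later years are not published and
default to the cardiovascular schedule, overridable via
`model_settings(stroke_annual_mortality=)`.

**Accrual and discounting.** In cycle *k* the start-of-cycle occupancies
accrue utilities and costs with discount factor $(1+r)^{-(k-1)}$ — the first
year undiscounted, no half-cycle correction — and are then advanced by the
cycle's transition matrix. This convention is what makes the effective
population of 6,440 yearly operations over 5 years at 3% equal exactly
30,378, the figure the analysis is built around, which is why it was chosen
over end-of-cycle accrual. A corollary, asserted in the tests: a cohort that
enters entirely dead accrues zero QALYs and exactly the one-off death cost
(below), and a deathless well cohort accrues its utility weight times the
annuity factor $\sum_{k=1}^{5}1.03^{-(k-1)} = 4.7171$.

## Parameters

`default_parameter_table()` encodes every model input with its distribution
family: Dirichlet for the mutually exclusive outcome vector, beta for
probabilities and utility weights, gamma (shape, scale) for costs and
utility decrements, lognormal (meanlog, sdlog) for relative risks, and fixed
values for deterministic rows. The complications relative risk is not
published as hyperparameters; it is fitted from the interim counts on the
log scale (`fit_lognormal_from_rr()`: meanlog = log RR, sdlog = SE of the
log RR), as the source analysis describes.

Four published rows are internally inconsistent — their hyperparameter means
disagree with their printed central estimates: the other-complications
utility decrement (Gamma(100, 0.0007), mean 0.07, printed 0.15), the renal
failure cost (Gamma(6, 1442), mean 8,652, printed 12,197), the
cardiovascular decrement (Gamma(298, 0.0006), mean 0.1788, printed 0.19,
5.9% off) and the confusion cost (Gamma(866, 9), mean 7,794, printed 7,961,
2.1% off). The package corrects none of them silently. The default
(`param_source = "hyperparams"`) samples the hyperparameters verbatim;
`param_source = "moments"` re-derives hyperparameters so the mean equals the
printed estimate while keeping each family's dispersion structure (gamma
shape, beta $a+b$, Dirichlet concentration, lognormal sdlog). The remaining
rows agree within 2%, which the test suite checks row by row.

Utility decrements are stored and sampled as positive magnitudes and applied
subtractively at use site; state utilities are floored at 0. Dead has
utility 0.

## Settings the published table leaves open

All of these are implementer assumptions, exposed in `model_settings()` and
echoed in the pipeline manifest; none is a published value.

* `standard_annual_mortality` (default **0.10**/year): annual mortality of
  the well state. The source model used unpublished age-adjusted standard
  mortality for a cohort of mean age ~85; 0.10 is a realistic round value
  for that age in a general population.
* `stroke_annual_mortality` (default `NULL` → cardiovascular schedule):
  post-stroke mortality beyond year 1, also unpublished registry data.
* `death_cost_every_cycle` (default `FALSE`): the published first-year
  after-hospital schedule prices "death" at €4,837. By default this is
  applied once, in cycle 1, to the fraction that died during the hospital
  episode (the €9,020 episode death cost applies in the tree); later deaths
  accrue nothing. Setting `TRUE` also charges it to new deaths in every
  later cycle. Whether the source model applied both the episode and the
  after-hospital death cost is not stated; the default applies both.
* `cv_cost_weights`, `other_cost_weights` (defaults unweighted): the tree
  has one branch per outcome group but costs are published per subtype, so
  the cardiovascular branch is priced as a weighted mean of the myocardial
  infarction and heart failure costs, and the other-complications branch as
  a weighted mean of its seven subtype costs. Mixing frequencies are not
  published; unweighted means are the neutral choice.
* Unlisted later-year costs (well, recovered) are read as zero; the
  "2 to 10 year" label on the late cost schedule is treated as its validity
  range, not the model horizon, which stays at 5 cycles.

## Numerical choices

* If a sampled pair of relative risks pushes the scaled death-plus-
  complication mass above 1 (practically unreachable at the published
  values), the scaled components are renormalized, uncomplicated is set to
  0, and the vector is flagged via the `"renormalized"` attribute. The same
  proportional rescaling guards the other-complications transition row if a
  sampled mortality and recovery probability were ever to sum above 1.
* Transition matrices and traces are validated to be row-stochastic within
  1e-9; violations raise internal-consistency errors rather than being
  repaired.
* Quadrant classification assigns exact zeros of the incremental cost or
  effect (a measure-zero event under the continuous draws) deterministically
  to the less-costly / more-effective side.
* `evpi_per_patient()` floors its result at zero to absorb floating-point
  negatives of order 1e-16; the quantity is non-negative by Jensen's
  inequality.
* The effective population is rounded down to a whole patient count.
* Seeds are explicit arguments everywhere; sampling restores the caller's
  RNG state, and the pipeline derives per-stage sub-seeds from the master
  seed so stage order cannot change results. Within a PSA iteration both
  strategies share one draw (common random numbers), so identical strategies
  give exactly zero increments and zero EVPI.

## Interim statistics

The relative risk uses the standard log-scale Wald interval with the exact
normal quantile and no continuity correction; zero events in either arm are
an explicit error. On the interim counts the formula gives a lower bound of
0.4645, which rounds to 0.465 where the trial report prints 0.464 — a
last-digit difference (truncation or a different rounding rule at source)
that is documented here and in the tests rather than chased.

The sample-size calculator uses the pooled-variance two-proportion normal
approximation (the formula `stats::power.prop.test()` solves iteratively;
the unpooled variant gives visibly different totals and was rejected because
it does not reproduce the pre-trial arithmetic). The `dilution` argument
scales the achievable risk *reduction* before the treatment-arm risk is
formed: effective RR $= 1 - d\,(1-RR)$. With the pre-trial inputs (control
risk 0.61, RR 0.63, 80% power, $\alpha$ = 0.05) the full effect needs ~152
patients, and dilution 0.57 — the share of complications assumed preventable
in this aged, comorbid population — gives ~468, consistent with the
announced 460-patient target, whose exact arithmetic is not published.

## What the synthetic data does and does not establish

`simulate_trial()` draws independent Bernoulli outcomes per arm (control arm
first) with a specified control risk and true relative risk: exactly the
data-generating process the interim table summarizes, with known ground
truth. Tests built on it verify estimator consistency and interval coverage.
It does not simulate complication subtypes, time-to-event outcomes,
within-patient correlation, or enrolment logistics, so green tests establish
the statistical machinery, not trial conduct. `toy_evpi_scenario()` provides
hand-enumerable decision problems ("two_point" has EVPI exactly 5,
"dominated" and "single_state" exactly 0) that the EVPI engine must
reproduce exactly; a brute-force enumeration written independently in the
test suite guards against the engine and its oracle sharing a bug.

## Known limitations

Several inputs of the original spreadsheet model are unpublished (standard
and post-stroke mortality, death-cost policy, cost-mixing weights), so the
PSA outputs are reconstruction-sensitive. The location of the incremental-
cost distribution is the sensitive quantity: the share of simulations in
which GDHT is both less costly and more effective, and the EVPI at high
willingness-to-pay, react to cost-side readings of the table (for instance,
whether the published per-outcome episode costs are totals, as implemented,
or increments over a base hospital-stay cost), while the EVPI at
€20,000/QALY and the population EVPI are comparatively robust. The
`scripts/acceptance.R` script recomputes all headline quantities from
scratch for inspection. The source report is itself not fully internally
consistent (its two statements of the same quadrant union differ by 1.8
percentage points, and the four parameter rows above), which bounds how
closely any reimplementation can be expected to match it. Within the
package, every such choice is a documented, overridable setting rather than
a hidden constant.
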