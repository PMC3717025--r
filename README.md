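# hipvoi

Value-of-information analysis for peroperative goal-directed hemodynamic
treatment (GDHT) versus routine fluid therapy in aged hip-fracture patients.

## The problem

An ongoing randomized trial compares GDHT with routine fluid therapy in
patients aged 70+ undergoing hip-fracture surgery. An interim look at the
first 99 patients (15/49 complications under GDHT vs 19/50 under routine
care) is statistically inconclusive — the 95% confidence interval for the
relative risk spans 1. The question a funder then faces is not "is GDHT
effective?" but "is it worth paying for more data?". This package answers
that question the way health economists do: it propagates all current
parameter uncertainty through a decision-analytic cost-effectiveness model
and prices the residual decision uncertainty as the expected value of
perfect information (EVPI). If the remaining cost of the trial is below the
population EVPI, continued data collection is potentially cost-effective.

It is aimed at health-economics and biostatistics users who want a
reproducible, scriptable version of this analysis: trial statisticians
revisiting an interim look, and modellers who want a tested EVPI engine with
a transparent Markov cohort model behind it.

## The model

* **Short-term decision tree.** After surgery a patient reaches one of five
  mutually exclusive outcomes — uncomplicated recovery, cardiovascular
  complication, stroke, other complication, or death — with routine-care
  probabilities drawn from a Dirichlet(52, 26, 2, 162, 160). Under GDHT the
  death probability is scaled by a lognormal mortality relative risk
  (meanlog −0.28, sdlog 0.09) and each complication probability by the
  complications relative risk fitted from the interim trial counts on the
  log scale (meanlog = log 0.806, sdlog = 0.281). Each outcome carries a
  gamma-distributed hospital episode cost; each strategy adds its delivery
  cost (€155 routine, €781 GDHT).
* **Markov cohort model.** The tree's outcome seeds a 5-state-plus-death
  annual cohort model run for 5 cycles: well, post-cardiovascular,
  post-stroke, post-other (from which recovery is possible), recovered, and
  absorbing death. State utilities are beta-distributed weights minus
  gamma-distributed decrements; costs follow the published first-year and
  later-year schedules. Costs and QALYs are discounted at 3% per year, first
  year undiscounted, no half-cycle correction.
* **PSA and EVPI.** A second-order Monte Carlo simulation draws one
  realization of every input per iteration and evaluates both strategies
  under the shared draw. With net monetary benefit `NB = λ·E − C` at
  willingness-to-pay `λ`, the per-patient EVPI is

  ```
  EVPI(λ) = E_θ[ max_s NB(s, θ) ] − max_s E_θ[ NB(s, θ) ]
  ```

  and the population EVPI multiplies it by the effective population
  `Σ_{k=1..L} I·(1+r)^−(k−1)` — the discounted number of future patients
  (6,440 operations/year over a 5-year technology lifetime at 3%: 30,378).

## Worked example

```r
library(hipvoi)

interim <- relative_risk(trial_counts(15, 49, 19, 50))
interim
#> Relative risk 0.806 (95% CI 0.465 to 1.397), SE(log RR) = 0.281

tab <- default_parameter_table()
psa <- run_psa(tab, n = 20000, seed = 1)
summary(psa)
#> PSA over 20000 iterations
#> Mean discounted cost (EUR): routine 12459  gdht 12125
#> Mean discounted QALYs:      routine 2.211  gdht 2.349
#> Cost-effectiveness plane quadrants:
#> more_effective_less_costly more_effective_more_costly
#>                       66.8                       28.3
#> less_effective_more_costly less_effective_less_costly
#>                        4.9                        0.0
#> Per-patient EVPI (EUR):
#> lambda=20000 lambda=50000
#>        215.6        263.0

evpi_curve(psa, lambda = c(0, 20000, 50000))
#> EVPI curve over 3 thresholds; effective population 30378 (6440/year, 5 years, 3% discount)
#>   lambda evpi_per_patient population_evpi
#> 1      0         298.8206         9077572
#> 2  20000         215.6060         6549680
#> 3  50000         263.0338         7990439
```

Reading the output: GDHT is on average cheaper (−€334) and more effective
(+0.138 QALYs), and is less costly *and* more effective in 66.8% of draws —
yet it is more costly and less effective in 4.9% of them, so a decision made
today carries risk. Eliminating that risk is worth about €216 per patient at
a €20,000/QALY threshold, or about €6.5 million over all patients facing the
decision during the technology's 5-year lifetime: the ceiling a funder
should be willing to pay for further research. The confidence interval
spanning 1 and the multi-million-euro EVPI are two readings of the same
uncertainty.

`plot(psa)` draws the cost-effectiveness plane and `plot(evpi_curve(psa))`
the EVPI against willingness to pay. `run_pipeline(voi_config(...))` runs
the whole chain and writes CSV/JSON artifacts plus a reproducibility
manifest; `simulate_trial()` and `toy_evpi_scenario()` generate synthetic
trials and hand-enumerable EVPI problems for testing. Assumption knobs for
inputs the published table leaves open live in `model_settings()` and are
documented in the vignette.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from a fresh 20,000-iteration PSA of the default parameter
table: the per-patient EVPI at €20,000 and €50,000 per QALY, the two
cost-effectiveness-plane quadrant percentages (less costly & more effective;
more costly & less effective), and the population EVPI in million euros at
€20,000 per QALY, writing them as JSON.
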