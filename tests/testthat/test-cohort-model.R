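pd <- point_draw(default_table)
strategies <- default_strategies(default_table)

test_that("delivery costs and the initial state distribution match the table", {
  expect_identical(strategies$routine$delivery_total, 11 + 27 + 117)  # 155
  expect_identical(strategies$gdht$delivery_total, 221 + 159 + 401)   # 781
  tree <- run_decision_tree(pd, strategies$routine)
  expect_equal(unname(tree$init[["dead"]]), 0.129)
  expect_equal(sum(tree$init), 1)
  expect_identical(unname(tree$init[["recovered"]]), 0)
  # expected short-term cost assembled by hand from the point estimates
  cv <- mean(c(pd$cost_mi, pd$cost_heart_failure))
  other <- mean(c(pd$cost_pneumonia, pd$cost_renal_failure, pd$cost_wound_infection,
                  pd$cost_dvt, pd$cost_pulmonary_embolism, pd$cost_gi_bleeding,
                  pd$cost_confusion))
  by_hand <- 155 + sum(pd$short_term_outcome *
                         c(pd$cost_death, cv, pd$cost_stroke, other,
                           pd$cost_no_complications))
  expect_equal(tree$cost, by_hand)
})

test_that("transition matrices are row-stochastic with absorbing death", {
  for (k in 1:5) {
    m <- transition_matrix(pd, k)
    expect_equal(unname(rowSums(m)), rep(1, 6))
    expect_true(all(m >= 0 & m <= 1))
    expect_identical(unname(m["dead", "dead"]), 1)
  }
  expect_equal(unname(transition_matrix(pd, 1)["cardiovascular", "dead"]), 0.107)
  expect_equal(unname(transition_matrix(pd, 2)["cardiovascular", "dead"]), 0.058)
  # year-3 value carried forward
  for (k in 3:5)
    expect_equal(unname(transition_matrix(pd, k)["cardiovascular", "dead"]), 0.056)
  expect_equal(unname(transition_matrix(pd, 1)["stroke", "dead"]), 0.15)
  expect_equal(unname(transition_matrix(pd, 2)["stroke", "dead"]), 0.058)
  s <- model_settings(stroke_annual_mortality = 0.2)
  expect_equal(unname(transition_matrix(pd, 2, s)["stroke", "dead"]), 0.2)
})

test_that("a deathless well cohort accrues the discounted annuity of its utility", {
  draw <- pd
  draw$cv_mortality_year1 <- draw$cv_mortality_year2 <- draw$cv_mortality_year3 <- 0
  draw$stroke_mortality_first_year <- 0
  draw$other_mortality <- 1e-12  # beta support excludes exact 0; negligible
  draw$other_recovery <- 1e-12
  draw$mortality_after_recovery <- 1e-12
  s <- model_settings(standard_annual_mortality = 0)
  init <- c(well = 1, cardiovascular = 0, stroke = 0, other = 0, recovered = 0, dead = 0)
  mk <- run_markov(init, draw, horizon = 5, discount = 0.03, settings = s)
  annuity <- sum(1.03^-(0:4))
  expect_equal(round(annuity, 4), 4.7171)
  expect_equal(mk$qaly, draw$utility_well * annuity, tolerance = 1e-9)
})

test_that("an all-dead cohort accrues no QALYs and only the one-off death cost", {
  init <- c(0, 0, 0, 0, 0, 1)
  mk <- run_markov(init, pd, horizon = 5, discount = 0.03)
  expect_identical(mk$qaly, 0)
  expect_equal(mk$cost, pd$fy_cost_death)  # 4837, applied once in cycle 1
  free <- pd; free$fy_cost_death <- 0
  expect_identical(run_markov(init, free, horizon = 5, discount = 0.03)$cost, 0)
})

test_that("discounting only shrinks totals and vanishes at rate zero", {
  init <- run_decision_tree(pd, strategies$routine)$init
  disc <- run_markov(init, pd, horizon = 5, discount = 0.03)
  undisc <- run_markov(init, pd, horizon = 5, discount = 0)
  expect_lt(disc$cost, undisc$cost)
  expect_lt(disc$qaly, undisc$qaly)
  expect_equal(undisc$cost, sum(undisc$cost_by_cycle))
  # one cycle, no discounting: expected values enumerate by hand over states
  one <- run_markov(init, pd, horizon = 1, discount = 0)
  u <- hipvoi:::utilities_vector(pd)
  sched <- hipvoi:::cost_schedule(pd, 1)
  expect_equal(one$qaly, sum(init * u))
  expect_equal(one$cost, sum(init * sched))
})

test_that("occupancies conserve mass and death is monotone across random draws", {
  draws <- sample_draws(default_table, 25, seed = 31)
  for (i in 1:25) {
    d <- hipvoi:::draw_from(draws, i)
    for (strat in strategies) {
      res <- evaluate_strategy(d, strat)
      expect_equal(unname(rowSums(res$trace)), rep(1, 6), tolerance = 1e-9)
      expect_true(all(res$trace >= 0))
      expect_true(all(diff(res$trace[, "dead"]) >= 0))
      expect_gte(res$cost, 0)
      expect_gte(res$qaly, 0)
      expect_lte(res$qaly, 5 * 1)  # horizon x maximal utility weight
    }
  }
})

test_that("QALYs never increase when any mortality input is perturbed upward", {
  base <- evaluate_strategy(pd, strategies$routine)$qaly
  bump <- function(field, eps = 0.05) {
    d <- pd; d[[field]] <- d[[field]] + eps
    evaluate_strategy(d, strategies$routine)$qaly
  }
  for (f in c("cv_mortality_year1", "cv_mortality_year2", "cv_mortality_year3",
              "stroke_mortality_first_year", "other_mortality",
              "mortality_after_recovery"))
    expect_lte(bump(f), base)
  worse <- evaluate_strategy(pd, strategies$routine,
                             settings = model_settings(standard_annual_mortality = 0.2))$qaly
  expect_lt(worse, base)
})

test_that("strategies differing only in delivery cost differ by exactly that", {
  d <- pd
  d$rr_complications <- 1
  d$rr_mortality <- 1
  routine <- evaluate_strategy(d, strategies$routine)
  gdht <- evaluate_strategy(d, strategies$gdht)
  expect_equal(gdht$cost - routine$cost, 781 - 155)
  expect_equal(gdht$qaly, routine$qaly)
  # and a point-estimate evaluation is bit-identical across calls
  expect_identical(evaluate_strategy(pd, strategies$gdht)$cost,
                   evaluate_strategy(pd, strategies$gdht)$cost)
})

test_that("the PSA hot path reproduces evaluate_strategy draw by draw", {
  draws <- sample_draws(default_table, 8, seed = 77)
  for (i in 1:8) {
    d <- hipvoi:::draw_from(draws, i)
    pair <- hipvoi:::evaluate_draw_pair(d, strategies, 5L, 0.03, model_settings())
    for (nm in c("routine", "gdht")) {
      ref <- evaluate_strategy(d, strategies[[nm]], discount = 0.03)
      expect_equal(unname(pair["cost", nm]), ref$cost)
      expect_equal(unname(pair["qaly", nm]), ref$qaly)
    }
  }
})
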