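#' Treatment strategy specification
#'
#' A strategy is identified by its name and its per-patient delivery cost
#' components (device, pre-operative staff, intra-anesthesia staff, in
#' euros). The `"gdht"` strategy additionally triggers the application of the
#' sampled relative risks to the routine short-term outcome vector inside the
#' decision tree.
#'
#' @param name `"routine"` or `"gdht"`.
#' @param device,preop_staff,anesthesia_staff Delivery cost components (EUR).
#' @return An object of class `"strategy_spec"`.
#' @export
strategy_spec <- function(name = c("routine", "gdht"), device, preop_staff,
                          anesthesia_staff) {
  name <- match.arg(name)
  costs <- c(device = device, preop_staff = preop_staff,
             anesthesia_staff = anesthesia_staff)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop_field("delivery costs", "must be finite and >= 0")
  structure(list(name = name, delivery = costs, delivery_total = sum(costs)),
            class = "strategy_spec")
}

#' Both strategies with delivery costs taken from a parameter table
#'
#' @param table A parameter table containing the six delivery-cost rows.
#' @return A named list with elements `routine` and `gdht`.
#' @examples
#' default_strategies()$gdht$delivery_total  # 221 + 159 + 401 = 781
#' @export
default_strategies <- function(table = default_parameter_table()) {
  p <- point_draw(table)
  list(
    routine = strategy_spec("routine", p$routine_device, p$routine_preop_staff,
                            p$routine_anesthesia_staff),
    gdht = strategy_spec("gdht", p$gdht_device, p$gdht_preop_staff,
                         p$gdht_anesthesia_staff))
}

#' Model settings for inputs the published table leaves open
#'
#' Assumption knobs for the cohort model, each an implementer default
#' standing in for an unpublished registry value (never a published number):
#'
#' @param standard_annual_mortality Annual death probability of the `well`
#'   and (via its own beta draw this does not apply to) states without a
#'   disease-specific schedule; default 0.10, an assumption for an age ~85
#'   general population.
#' @param stroke_annual_mortality Post-stroke annual mortality for cycles 2
#'   onward; `NULL` (default) follows the cardiovascular schedule.
#' @param death_cost_every_cycle If `FALSE` (default) the first-year
#'   after-hospital death cost is applied once, to the fraction of the
#'   cohort that died during the hospital episode; if `TRUE` it is also
#'   applied to new deaths in every later cycle.
#' @param cv_cost_weights Mixing weights for the cardiovascular episode cost
#'   over (myocardial infarction, heart failure); default unweighted.
#' @param other_cost_weights Mixing weights for the other-complications
#'   episode cost over (pneumonia, renal failure, wound infection,
#'   deep-vein thrombosis, pulmonary embolism, GI bleeding, confusion);
#'   default unweighted.
#' @return An object of class `"model_settings"`.
#' @export
model_settings <- function(standard_annual_mortality = 0.10,
                           stroke_annual_mortality = NULL,
                           death_cost_every_cycle = FALSE,
                           cv_cost_weights = c(0.5, 0.5),
                           other_cost_weights = rep(1 / 7, 7)) {
  check_prob(standard_annual_mortality, "standard_annual_mortality", open = FALSE)
  if (!is.null(stroke_annual_mortality))
    check_prob(stroke_annual_mortality, "stroke_annual_mortality", open = FALSE)
  if (!isTRUE(death_cost_every_cycle) && !isFALSE(death_cost_every_cycle))
    stop_field("death_cost_every_cycle", "must be TRUE or FALSE")
  for (w in list(cv = cv_cost_weights, other = other_cost_weights))
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop_field("cost weights", "must be non-negative and sum to 1")
  if (length(cv_cost_weights) != 2L) stop_field("cv_cost_weights", "needs 2 weights")
  if (length(other_cost_weights) != 7L) stop_field("other_cost_weights", "needs 7 weights")
  structure(list(standard_annual_mortality = standard_annual_mortality,
                 stroke_annual_mortality = stroke_annual_mortality,
                 death_cost_every_cycle = death_cost_every_cycle,
                 cv_cost_weights = cv_cost_weights,
                 other_cost_weights = other_cost_weights),
            class = "model_settings")
}

#' Short-term decision tree
#'
#' Evaluates the hospital episode for one strategy under one parameter draw.
#' For `"gdht"` the sampled relative risks are applied to the routine outcome
#' vector via [gdht_probabilities()]. The expected short-term cost is the
#' strategy's delivery cost plus the probability-weighted sampled episode
#' costs; the grouped branches price cardiovascular complications as a
#' weighted mean of the myocardial-infarction and heart-failure costs and
#' other complications as a weighted mean of its seven component costs. The
#' outcome vector then seeds the Markov model: uncomplicated -> well,
#' cardiovascular -> cardiovascular, stroke -> stroke, other -> other,
#' death -> dead. No QALYs accrue in the tree.
#'
#' @param draw A parameter draw ([sample_draw()] or [point_draw()]).
#' @param strategy A [strategy_spec()].
#' @param settings A [model_settings()].
#' @return A list with `cost` (EUR), `init` (length-6 initial state
#'   distribution), and `probabilities` (the length-5 outcome vector used).
#' @examples
#' tab <- default_parameter_table()
#' run_decision_tree(point_draw(tab), default_strategies(tab)$routine)
#' @export
run_decision_tree <- function(draw, strategy, settings = model_settings()) {
  stopifnot(inherits(strategy, "strategy_spec"))
  p <- if (strategy$name == "gdht") {
    gdht_probabilities(draw$short_term_outcome, draw$rr_complications,
                       draw$rr_mortality)
  } else {
    stats::setNames(draw$short_term_outcome, outcome_names)
  }
  episode <- c(
    death = draw$cost_death,
    cardiovascular = sum(settings$cv_cost_weights *
                           c(draw$cost_mi, draw$cost_heart_failure)),
    stroke = draw$cost_stroke,
    other = sum(settings$other_cost_weights *
                  c(draw$cost_pneumonia, draw$cost_renal_failure,
                    draw$cost_wound_infection, draw$cost_dvt,
                    draw$cost_pulmonary_embolism, draw$cost_gi_bleeding,
                    draw$cost_confusion)),
    uncomplicated = draw$cost_no_complications)
  init <- stats::setNames(
    c(p[["uncomplicated"]], p[["cardiovascular"]], p[["stroke"]],
      p[["other"]], 0, p[["death"]]), state_names)
  list(cost = strategy$delivery_total + sum(p * episode),
       init = init, probabilities = p)
}

#' Annual transition matrix
#'
#' Row-stochastic transition matrix over the six states \{well,
#' cardiovascular, stroke, other, recovered, dead\} for a given cycle.
#' Post-cardiovascular mortality follows the published schedule 0.107 /
#' 0.058 / 0.056 for cycles 1/2/3, carried forward thereafter. Post-stroke
#' mortality is 0.15 in cycle 1 and then follows the cardiovascular schedule
#' unless `settings$stroke_annual_mortality` overrides it. The
#' other-complications state resolves by the sampled mortality and recovery
#' probabilities; recovered patients face the sampled post-recovery
#' mortality; well patients face the configured standard annual mortality;
#' death is absorbing.
#'
#' @param draw A parameter draw.
#' @param cycle 1-based cycle index.
#' @param settings A [model_settings()].
#' @return A 6 x 6 row-stochastic matrix with state dimnames.
#' @export
transition_matrix <- function(draw, cycle, settings = model_settings()) {
  cycle <- check_count(cycle, "cycle")
  cv_sched <- c(draw$cv_mortality_year1, draw$cv_mortality_year2,
                draw$cv_mortality_year3)
  cv_m <- cv_sched[min(cycle, 3L)]
  stroke_m <- if (cycle == 1L) draw$stroke_mortality_first_year
              else if (!is.null(settings$stroke_annual_mortality))
                settings$stroke_annual_mortality
              else cv_sched[min(cycle, 3L)]
  d_other <- draw$other_mortality
  r_other <- draw$other_recovery
  if (d_other + r_other > 1) {  # tail guard; unreachable at published values
    s <- d_other + r_other
    d_other <- d_other / s
    r_other <- r_other / s
  }
  sm <- settings$standard_annual_mortality
  m <- matrix(0, 6L, 6L, dimnames = list(state_names, state_names))
  m["well", "well"] <- 1 - sm;            m["well", "dead"] <- sm
  m["cardiovascular", "cardiovascular"] <- 1 - cv_m
  m["cardiovascular", "dead"] <- cv_m
  m["stroke", "stroke"] <- 1 - stroke_m;  m["stroke", "dead"] <- stroke_m
  m["other", "dead"] <- d_other
  m["other", "recovered"] <- r_other
  m["other", "other"] <- 1 - d_other - r_other
  m["recovered", "recovered"] <- 1 - draw$mortality_after_recovery
  m["recovered", "dead"] <- draw$mortality_after_recovery
  m["dead", "dead"] <- 1
  if (any(abs(rowSums(m) - 1) > 1e-9) || any(m < 0))
    stop("internal consistency error: transition matrix rows must be probabilities summing to 1",
         call. = FALSE)
  m
}

# State utility weights implied by a draw: decrements are applied
# subtractively to the well-state weight and floored at 0; death is 0.
utilities_vector <- function(draw) {
  u <- draw$utility_well
  stats::setNames(
    pmax(c(u, u - draw$decrement_cv, u - draw$decrement_stroke,
           u - draw$decrement_other, draw$utility_recovered, 0), 0),
    state_names)
}

# Per-state annual cost schedule: cycle 1 uses the first-year-after-hospital
# list (including the one-off death cost on the hospital-episode deaths);
# later cycles use the 2-to-10-year list, with unlisted states costing 0.
cost_schedule <- function(draw, cycle) {
  if (cycle == 1L) {
    c(well = draw$fy_cost_well, cardiovascular = draw$fy_cost_cv,
      stroke = draw$fy_cost_stroke, other = draw$fy_cost_other,
      recovered = draw$fy_cost_recovered, dead = draw$fy_cost_death)
  } else {
    c(well = 0, cardiovascular = draw$lt_cost_cv, stroke = draw$lt_cost_stroke,
      other = draw$lt_cost_other, recovered = 0, dead = 0)
  }
}

#' Run the Markov cohort model
#'
#' Propagates an initial state distribution through `horizon` annual cycles.
#' In cycle \eqn{k} the start-of-cycle occupancies accrue that cycle's
#' utilities and costs with discount factor \eqn{(1+r)^{-(k-1)}} (the first
#' year is undiscounted; no half-cycle correction), and are then advanced by
#' the cycle's [transition_matrix()].
#'
#' @param init Length-6 initial distribution over the states (on the
#'   simplex), typically from [run_decision_tree()].
#' @param draw A parameter draw.
#' @param horizon Number of annual cycles, default 5.
#' @param discount Annual discount rate, default the draw's `discount_rate`.
#' @param settings A [model_settings()].
#' @return A list with `trace` (a `(horizon+1) x 6` occupancy matrix whose
#'   row `k` is the distribution at the start of cycle `k`), per-cycle
#'   discounted `cost_by_cycle` and `qaly_by_cycle`, and totals `cost` and
#'   `qaly`.
#' @export
run_markov <- function(init, draw, horizon = 5L, discount = draw$discount_rate,
                       settings = model_settings()) {
  horizon <- check_count(horizon, "horizon")
  if (length(init) != 6L || any(init < -1e-12) || abs(sum(init) - 1) > 1e-9)
    stop_field("init", "must be a length-6 distribution summing to 1")
  if (!is.numeric(discount) || discount < 0)
    stop_field("discount", "must be >= 0")
  mats <- lapply(seq_len(horizon), function(k) transition_matrix(draw, k, settings))
  u <- utilities_vector(draw)
  trace <- matrix(0, horizon + 1L, 6L,
                  dimnames = list(paste0("cycle", 0:horizon), state_names))
  trace[1L, ] <- init
  cost_k <- qaly_k <- numeric(horizon)
  for (k in seq_len(horizon)) {
    df <- (1 + discount)^(-(k - 1L))
    cur <- trace[k, ]
    qaly_k[k] <- sum(cur * u) * df
    cost_k[k] <- sum(cur * cost_schedule(draw, k)) * df
    nxt <- as.vector(cur %*% mats[[k]])
    if (settings$death_cost_every_cycle && k >= 2L)
      cost_k[k] <- cost_k[k] + (nxt[6L] - cur[6L]) * draw$fy_cost_death * df
    trace[k + 1L, ] <- nxt
  }
  if (any(abs(rowSums(trace) - 1) > 1e-9))
    stop("internal consistency error: occupancies must sum to 1 each cycle",
         call. = FALSE)
  list(trace = trace, cost_by_cycle = cost_k, qaly_by_cycle = qaly_k,
       cost = sum(cost_k), qaly = sum(qaly_k))
}

#' Evaluate one strategy under one parameter draw
#'
#' Composes the short-term decision tree (hospital episode, cycle 0,
#' undiscounted) with the 5-cycle Markov model (long-term flows discounted
#' from cycle 1 with the first year undiscounted).
#'
#' @inheritParams run_decision_tree
#' @inheritParams run_markov
#' @return A list with total discounted `cost` (EUR), total discounted
#'   `qaly`, the `short_term_cost` component, and the Markov `trace`.
#' @examples
#' tab <- default_parameter_table()
#' evaluate_strategy(point_draw(tab), default_strategies(tab)$routine)$qaly
#' @export
evaluate_strategy <- function(draw, strategy, horizon = 5L,
                              discount = draw$discount_rate,
                              settings = model_settings()) {
  tree <- run_decision_tree(draw, strategy, settings)
  mk <- run_markov(tree$init, draw, horizon = horizon, discount = discount,
                   settings = settings)
  list(cost = tree$cost + mk$cost, qaly = mk$qaly,
       short_term_cost = tree$cost, trace = mk$trace)
}

# Lean shared-matrices evaluation of both strategies for one draw; the PSA
# hot path. Logic mirrors run_decision_tree/run_markov exactly (asserted in
# the test suite) but skips trace bookkeeping.
evaluate_draw_pair <- function(draw, strategies, horizon, discount, settings) {
  mats <- lapply(seq_len(horizon), function(k) transition_matrix(draw, k, settings))
  u <- utilities_vector(draw)
  scheds <- lapply(seq_len(horizon), function(k) cost_schedule(draw, k))
  dfs <- (1 + discount)^(-(seq_len(horizon) - 1L))
  vapply(strategies, function(strategy) {
    tree <- run_decision_tree(draw, strategy, settings)
    cur <- tree$init
    cost <- tree$cost
    qaly <- 0
    for (k in seq_len(horizon)) {
      qaly <- qaly + sum(cur * u) * dfs[k]
      cost <- cost + sum(cur * scheds[[k]]) * dfs[k]
      nxt <- as.vector(cur %*% mats[[k]])
      if (settings$death_cost_every_cycle && k >= 2L)
        cost <- cost + (nxt[6L] - cur[6L]) * draw$fy_cost_death * dfs[k]
      cur <- nxt
    }
    c(cost = cost, qaly = qaly)
  }, numeric(2L))
}
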