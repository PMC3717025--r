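#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the decision tree and Markov
#' cohort model. Each iteration draws one realization of every model input
#' and evaluates both strategies under that shared draw (common random
#' numbers: the two arms differ only through the delivery costs and the
#' application of the sampled relative risks), yielding one discounted
#' (cost, QALY) pair per strategy and the incremental quantities
#' \eqn{\Delta C = C_{GDHT} - C_{Routine}} and
#' \eqn{\Delta E = E_{GDHT} - E_{Routine}}.
#'
#' @param table A parameter table, e.g. [default_parameter_table()].
#' @param n Number of Monte Carlo iterations; the published analysis used
#'   1,000 (the default). Use 20,000+ to push Monte Carlo error below
#'   reporting precision.
#' @param seed Optional RNG seed (restored on exit); fixed seed gives a
#'   bit-identical sample.
#' @param horizon Markov cycles, default 5.
#' @param discount Annual discount rate; defaults to the table's
#'   `discount_rate` entry (0.03).
#' @param settings A [model_settings()].
#' @param strategies Named list of the two [strategy_spec()]s; default
#'   [default_strategies()] on `table`.
#' @return An object of class `"gdht_psa"`: a list with `n x 2` matrices
#'   `cost` and `qaly` (columns `routine`, `gdht`), vectors `delta_cost` and
#'   `delta_qaly`, the iteration count `n`, `seed`, `horizon`, `discount`,
#'   `settings`, and the parameter-table `fingerprint`.
#' @examples
#' psa <- run_psa(default_parameter_table(), n = 100, seed = 1)
#' summary(psa)
#' @export
run_psa <- function(table, n = 1000L, seed = NULL, horizon = 5L,
                    discount = NULL, settings = model_settings(),
                    strategies = default_strategies(table)) {
  validate_parameter_table(table)
  n <- check_count(n, "n")
  horizon <- check_count(horizon, "horizon")
  if (is.null(discount)) discount <- table[["discount_rate"]]$point
  stopifnot(inherits(settings, "model_settings"),
            all(c("routine", "gdht") %in% names(strategies)))
  strategies <- strategies[c("routine", "gdht")]
  draws <- sample_draws(table, n, seed = seed)
  cost <- qaly <- matrix(NA_real_, n, 2L,
                         dimnames = list(NULL, c("routine", "gdht")))
  for (i in seq_len(n)) {
    res <- evaluate_draw_pair(draw_from(draws, i), strategies, horizon,
                              discount, settings)
    cost[i, ] <- res["cost", ]
    qaly[i, ] <- res["qaly", ]
  }
  structure(
    list(cost = cost, qaly = qaly,
         delta_cost = cost[, "gdht"] - cost[, "routine"],
         delta_qaly = qaly[, "gdht"] - qaly[, "routine"],
         n = n, seed = seed, horizon = horizon, discount = discount,
         settings = settings, fingerprint = table_fingerprint(table)),
    class = "gdht_psa")
}

#' @export
print.gdht_psa <- function(x, ...) {
  cat(sprintf("PSA sample: %d iterations (table %s)\n", x$n, x$fingerprint))
  cat(sprintf("  mean incremental cost (GDHT - routine): %.1f EUR\n",
              mean(x$delta_cost)))
  cat(sprintf("  mean incremental QALYs:                 %.4f\n",
              mean(x$delta_qaly)))
  invisible(x)
}

#' @export
summary.gdht_psa <- function(object, lambda = c(20000, 50000), ...) {
  q <- ce_plane_quadrants(object)
  evpi <- vapply(lambda, function(l)
    evpi_per_patient(net_benefit(object, l)), numeric(1))
  out <- list(n = object$n,
              mean_cost = colMeans(object$cost),
              mean_qaly = colMeans(object$qaly),
              mean_delta_cost = mean(object$delta_cost),
              mean_delta_qaly = mean(object$delta_qaly),
              quadrants = q,
              evpi = stats::setNames(evpi, paste0("lambda=", lambda)))
  class(out) <- "summary.gdht_psa"
  out
}

#' @export
print.summary.gdht_psa <- function(x, ...) {
  cat(sprintf("PSA over %d iterations\n", x$n))
  cat("Mean discounted cost (EUR): routine", sprintf("%.0f", x$mean_cost["routine"]),
      " gdht", sprintf("%.0f", x$mean_cost["gdht"]), "\n")
  cat("Mean discounted QALYs:      routine", sprintf("%.3f", x$mean_qaly["routine"]),
      " gdht", sprintf("%.3f", x$mean_qaly["gdht"]), "\n")
  cat("Cost-effectiveness plane quadrants:\n")
  print(round(100 * x$quadrants, 1))
  cat("Per-patient EVPI (EUR):\n")
  print(round(x$evpi, 1))
  invisible(x)
}

#' Cost-effectiveness plane scatter
#'
#' @param x A `"gdht_psa"` object.
#' @param lambda Willingness-to-pay threshold drawn as a reference line
#'   through the origin (EUR/QALY); default 20000.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gdht_psa <- function(x, lambda = 20000, ...) {
  graphics::plot(x$delta_qaly, x$delta_cost,
                 xlab = expression(Delta * "QALYs (GDHT - routine)"),
                 ylab = expression(Delta * "cost (EUR)"),
                 pch = 16, cex = 0.4, col = "grey40", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(0, lambda, lty = 2)
  invisible(x)
}

#' Quadrant proportions of the cost-effectiveness plane
#'
#' Classifies each PSA iteration by the signs of the incremental effect and
#' incremental cost. Exact zeros (a measure-zero event) are deterministically
#' assigned to the more-effective / less-costly side.
#'
#' @param sample A `"gdht_psa"` object.
#' @return A named length-4 proportion vector over
#'   `more_effective_less_costly`, `more_effective_more_costly`,
#'   `less_effective_more_costly`, `less_effective_less_costly`; sums to 1.
#' @export
ce_plane_quadrants <- function(sample) {
  stopifnot(inherits(sample, "gdht_psa"))
  de <- sample$delta_qaly >= 0
  dc <- sample$delta_cost <= 0
  c(more_effective_less_costly = mean(de & dc),
    more_effective_more_costly = mean(de & !dc),
    less_effective_more_costly = mean(!de & !dc),
    less_effective_less_costly = mean(!de & dc))
}

#' Net monetary benefit matrix
#'
#' \eqn{NB = \lambda \times QALYs - cost} per iteration and strategy, with
#' \eqn{\lambda} the willingness-to-pay threshold (EUR per QALY).
#'
#' @param sample A `"gdht_psa"` object.
#' @param lambda Willingness-to-pay, >= 0.
#' @return An `n x 2` matrix with columns `routine` and `gdht`.
#' @export
net_benefit <- function(sample, lambda) {
  stopifnot(inherits(sample, "gdht_psa"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop_field("lambda", "must be a single number >= 0")
  lambda * sample$qaly - sample$cost
}

#' Per-patient expected value of perfect information
#'
#' The mean over iterations of the best achievable net benefit minus the net
#' benefit of the strategy that is best on average:
#' \eqn{EVPI = E_\theta[\max_s NB(s,\theta)] - \max_s E_\theta[NB(s,\theta)]}.
#' This is the expected cost of deciding under current information, i.e. the
#' per-decision ceiling on the value of further research. It is non-negative
#' by Jensen's inequality.
#'
#' @param nb A net-benefit matrix (iterations x strategies) as returned by
#'   [net_benefit()], or a [toy_evpi_scenario()] whose enumerated states are
#'   used as equally weighted iterations.
#' @return EVPI in EUR per patient (>= 0).
#' @examples
#' evpi_per_patient(toy_evpi_scenario("two_point"))  # 5
#' @export
evpi_per_patient <- function(nb) {
  if (inherits(nb, "toy_evpi_scenario")) nb <- nb$nb
  nb <- as.matrix(nb)
  if (nrow(nb) < 1L || ncol(nb) < 2L)
    stop_field("nb", "needs at least one iteration and two strategies")
  max(mean(apply(nb, 1L, max)) - max(colMeans(nb)), 0)
}

#' Effective population over a technology's lifetime
#'
#' The discounted number of future patients facing the treatment decision:
#' \eqn{\sum_{k=1}^{L} I \, (1+r)^{-(k-1)}} for annual incidence \eqn{I},
#' lifetime \eqn{L} years and discount rate \eqn{r} (first year
#' undiscounted), rounded down to a whole number of patients.
#'
#' @param annual_incidence Patients per year facing the decision.
#' @param lifetime Expected lifetime of the technology in years, >= 1.
#' @param discount Annual discount rate, >= 0.
#' @return Integer patient count.
#' @examples
#' effective_population(6440, 5, 0.03)  # 30378
#' @export
effective_population <- function(annual_incidence, lifetime, discount) {
  check_count(lifetime, "lifetime")
  if (!is.numeric(annual_incidence) || annual_incidence < 0)
    stop_field("annual_incidence", "must be >= 0")
  if (!is.numeric(discount) || discount < 0)
    stop_field("discount", "must be >= 0")
  as.integer(floor(sum(annual_incidence * (1 + discount)^(-(seq_len(lifetime) - 1L)))))
}

#' EVPI across a willingness-to-pay grid
#'
#' Per-patient and population EVPI at each threshold on a grid, with
#' population EVPI = per-patient EVPI x [effective_population()].
#'
#' @param sample A `"gdht_psa"` object.
#' @param lambda Non-negative, sorted willingness-to-pay grid (EUR/QALY);
#'   default 0 to 100,000 in steps of 1,000.
#' @param annual_incidence,lifetime,discount Effective-population inputs;
#'   defaults 6,440 operations/year, 5 years, 3%.
#' @return An object of classes `"evpi_curve"` and `"data.frame"` with
#'   columns `lambda`, `evpi_per_patient`, `population_evpi`, and attributes
#'   `effective_population`, `annual_incidence`, `lifetime`, `discount`.
#' @examples
#' psa <- run_psa(default_parameter_table(), n = 200, seed = 1)
#' head(evpi_curve(psa, lambda = c(0, 20000, 50000)))
#' @export
evpi_curve <- function(sample, lambda = seq(0, 100000, by = 1000),
                       annual_incidence = 6440, lifetime = 5, discount = 0.03) {
  stopifnot(inherits(sample, "gdht_psa"))
  if (length(lambda) < 1L || any(lambda < 0) || is.unsorted(lambda))
    stop_field("lambda", "must be a non-empty, non-negative, sorted grid")
  pop <- effective_population(annual_incidence, lifetime, discount)
  per_patient <- vapply(lambda, function(l)
    evpi_per_patient(net_benefit(sample, l)), numeric(1))
  out <- data.frame(lambda = lambda, evpi_per_patient = per_patient,
                    population_evpi = per_patient * pop)
  structure(out, class = c("evpi_curve", "data.frame"),
            effective_population = pop, annual_incidence = annual_incidence,
            lifetime = lifetime, discount = discount)
}

#' @export
print.evpi_curve <- function(x, ...) {
  cat(sprintf("EVPI curve over %d thresholds; effective population %d (%g/year, %d years, %g%% discount)\n",
              nrow(x), attr(x, "effective_population"),
              attr(x, "annual_incidence"), attr(x, "lifetime"),
              100 * attr(x, "discount")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @param x An `"evpi_curve"` object.
#' @param population Plot population (default) or per-patient EVPI.
#' @param ... Passed to [graphics::plot()].
#' @rdname evpi_curve
#' @export
plot.evpi_curve <- function(x, population = TRUE, ...) {
  y <- if (population) x$population_evpi / 1e6 else x$evpi_per_patient
  graphics::plot(x$lambda, y, type = "l",
                 xlab = "Willingness to pay (EUR/QALY)",
                 ylab = if (population) "Population EVPI (million EUR)"
                        else "EVPI per patient (EUR)", ...)
  invisible(x)
}
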