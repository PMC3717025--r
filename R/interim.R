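#' Relative risk with a log-scale Wald confidence interval
#'
#' Intention-to-treat relative risk of the treatment arm versus the control
#' arm, with the standard Wald interval on the log scale:
#' \deqn{\widehat{RR} = \frac{e_t/n_t}{e_c/n_c}, \qquad
#'   SE(\log \widehat{RR}) = \sqrt{1/e_t - 1/n_t + 1/e_c - 1/n_c},}
#' and CI \eqn{\exp(\log\widehat{RR} \pm z \, SE)} with \eqn{z} the exact
#' standard-normal quantile for the requested level. No continuity correction
#' is applied; zero events in either arm are an error rather than being
#' silently adjusted.
#'
#' @param counts A [trial_counts()] object.
#' @param level Confidence level, default 0.95.
#' @return An object of class `"relative_risk"` with components `rr`,
#'   `log_rr`, `se_log_rr`, `ci_low`, `ci_high`, `level`, and the input
#'   `counts`.
#' @examples
#' relative_risk(trial_counts(15, 49, 19, 50))
#' @export
relative_risk <- function(counts, level = 0.95) {
  if (!inherits(counts, "trial_counts"))
    stop("`counts` must be a trial_counts object", call. = FALSE)
  check_prob(level, "level")
  if (counts$events_treatment < 1L)
    stop_field("events_treatment", "relative risk requires at least one event in the treatment arm")
  if (counts$events_control < 1L)
    stop_field("events_control", "relative risk requires at least one event in the control arm")
  rr <- (counts$events_treatment / counts$n_treatment) /
    (counts$events_control / counts$n_control)
  se <- sqrt(1 / counts$events_treatment - 1 / counts$n_treatment +
               1 / counts$events_control - 1 / counts$n_control)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(rr = rr, log_rr = log(rr), se_log_rr = se,
         ci_low = exp(log(rr) - z * se), ci_high = exp(log(rr) + z * se),
         level = level, counts = counts),
    class = "relative_risk")
}

#' @export
print.relative_risk <- function(x, digits = 3, ...) {
  cat(sprintf("Relative risk %s (%g%% CI %s to %s), SE(log RR) = %s\n",
              format(round(x$rr, digits)), 100 * x$level,
              format(round(x$ci_low, digits)), format(round(x$ci_high, digits)),
              format(round(x$se_log_rr, digits))))
  invisible(x)
}

#' Sample size for comparing two proportions
#'
#' Total sample size (both groups, 1:1 allocation) for detecting a relative
#' risk `rr` against a control-arm risk `p_control`, using the classic
#' pooled-variance normal approximation (Fleiss, without continuity
#' correction), the same formula solved iteratively by
#' [stats::power.prop.test()]:
#' \deqn{n/\mathrm{group} = \left(\frac{z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{\mathrm{power}}\sqrt{p_1 q_1 + p_2 q_2}}{|p_1 - p_2|}\right)^2.}
#'
#' A `dilution` factor scales the achievable risk reduction before the
#' treatment-arm risk is formed: the effective relative risk is
#' `1 - dilution * (1 - rr)`, so `dilution = 1` uses `rr` as given while
#' e.g. `dilution = 0.57` assumes only 57% of the complications are
#' preventable in this population (age and comorbidity).
#'
#' @param p_control Control-arm event probability.
#' @param rr Anticipated relative risk, in (0, 1).
#' @param power Desired power, default 0.8.
#' @param alpha Two-sided type I error, default 0.05.
#' @param dilution Fraction of the risk reduction assumed realizable, in
#'   (0, 1]; default 1.
#' @return Total sample size (2 x per-group n, each rounded up).
#' @examples
#' sample_size_two_proportions(0.61, 0.63)                  # ~152
#' sample_size_two_proportions(0.61, 0.63, dilution = 0.57) # ~468
#' @export
sample_size_two_proportions <- function(p_control, rr, power = 0.8,
                                        alpha = 0.05, dilution = 1) {
  check_prob(p_control, "p_control")
  check_prob(power, "power")
  check_prob(alpha, "alpha")
  if (!is.numeric(rr) || length(rr) != 1L || !is.finite(rr) || rr <= 0 || rr >= 1)
    stop_field("rr", "must lie in (0, 1); rr >= 1 gives no detectable reduction")
  if (!is.numeric(dilution) || length(dilution) != 1L || dilution <= 0 || dilution > 1)
    stop_field("dilution", "must lie in (0, 1]")
  rr_eff <- 1 - dilution * (1 - rr)
  p_treat <- p_control * rr_eff
  delta <- p_control - p_treat
  if (delta <= .Machine$double.eps)
    stop_field("rr", "effective risk difference is zero; required n is infinite")
  p_bar <- (p_control + p_treat) / 2
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n_group <- ((z_a * sqrt(2 * p_bar * (1 - p_bar)) +
                 z_b * sqrt(p_control * (1 - p_control) + p_treat * (1 - p_treat))) /
                delta)^2
  2L * as.integer(ceiling(n_group))
}
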