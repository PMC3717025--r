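#' Two-arm binary trial counts
#'
#' Container for the 2x2 table of a two-arm trial with a binary outcome
#' (post-operative complication including in-hospital death). The interim
#' data of the motivating trial are `trial_counts(15, 49, 19, 50)`.
#'
#' @param events_treatment,n_treatment Events and patients in the treatment
#'   (GDHT) arm.
#' @param events_control,n_control Events and patients in the control
#'   (routine fluid therapy) arm.
#' @return An object of class `"trial_counts"`.
#' @examples
#' trial_counts(15, 49, 19, 50)
#' @export
trial_counts <- function(events_treatment, n_treatment, events_control, n_control) {
  n_treatment <- check_count(n_treatment, "n_treatment")
  n_control <- check_count(n_control, "n_control")
  events_treatment <- check_count(events_treatment, "events_treatment", positive = FALSE)
  events_control <- check_count(events_control, "events_control", positive = FALSE)
  if (events_treatment > n_treatment)
    stop_field("events_treatment", "cannot exceed n_treatment")
  if (events_control > n_control)
    stop_field("events_control", "cannot exceed n_control")
  structure(
    list(events_treatment = events_treatment, n_treatment = n_treatment,
         events_control = events_control, n_control = n_control),
    class = "trial_counts")
}

#' @export
print.trial_counts <- function(x, ...) {
  cat("Two-arm trial counts\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.trial_counts <- function(x, ...) {
  data.frame(arm = c("treatment", "control"),
             events = c(x$events_treatment, x$events_control),
             total = c(x$n_treatment, x$n_control))
}

#' Simulate a two-arm randomized trial with a binary outcome
#'
#' Emulates the data-generating process of a 1:1 randomized trial in which
#' each patient independently experiences a complication with probability
#' `p_control` in the control arm and `true_rr * p_control` in the treatment
#' arm. The control arm is drawn first, then the treatment arm, so results
#' are bit-reproducible for a fixed `seed`.
#'
#' @param n_per_arm Patients per arm.
#' @param p_control Complication probability in the control arm, in (0, 1).
#' @param true_rr True relative risk (treatment vs control), >= 0 and such
#'   that `true_rr * p_control <= 1`.
#' @param seed Optional RNG seed; the caller's RNG state is restored on exit.
#' @return A [trial_counts()] object.
#' @examples
#' simulate_trial(50, p_control = 0.38, true_rr = 0.806, seed = 1)
#' @export
simulate_trial <- function(n_per_arm, p_control, true_rr, seed = NULL) {
  n_per_arm <- check_count(n_per_arm, "n_per_arm")
  check_prob(p_control, "p_control")
  if (!is.numeric(true_rr) || length(true_rr) != 1L || !is.finite(true_rr) || true_rr < 0)
    stop_field("true_rr", "must be a single number >= 0")
  if (true_rr * p_control > 1)
    stop_field("true_rr", "true_rr * p_control must not exceed 1")
  with_seed(seed, {
    events_control <- stats::rbinom(1L, n_per_arm, p_control)
    events_treatment <- stats::rbinom(1L, n_per_arm, true_rr * p_control)
    trial_counts(events_treatment, n_per_arm, events_control, n_per_arm)
  })
}

# EVPI by exhaustive enumeration over a finite, equally weighted state space:
# E over states of the best achievable net benefit, minus the net benefit of
# the best on-average strategy. Deliberately independent of the PSA engine so
# it can serve as its oracle.
enumerate_evpi <- function(nb) {
  nb <- as.matrix(nb)
  mean(apply(nb, 1L, max)) - max(colMeans(nb))
}

#' Toy scenarios with analytically known EVPI
#'
#' Small, hand-enumerable decision problems used to validate the EVPI engine.
#' Each scenario is a finite set of equally weighted parameter states with a
#' net monetary benefit per strategy in each state; its expected value of
#' perfect information is computed by exhaustive enumeration and stored
#' alongside the states.
#'
#' Available kinds:
#' \describe{
#'   \item{`"two_point"`}{Strategy A yields 0 in both states; strategy B
#'     yields +10 or -10 with equal probability. EVPI = 5 exactly.}
#'   \item{`"dominated"`}{Strategy B beats A in every state, so perfect
#'     information cannot change the decision. EVPI = 0.}
#'   \item{`"single_state"`}{One state only: no residual uncertainty.
#'     EVPI = 0.}
#' }
#'
#' @param kind Scenario label, one of `"two_point"`, `"dominated"`,
#'   `"single_state"`.
#' @return An object of class `"toy_evpi_scenario"`: a list with the strategy
#'   labels, the state-by-strategy net-benefit matrix `nb`, equal state
#'   `weights`, and the enumerated `evpi`.
#' @examples
#' toy_evpi_scenario("two_point")$evpi  # 5
#' @export
toy_evpi_scenario <- function(kind = c("two_point", "dominated", "single_state")) {
  kind <- match.arg(kind)
  nb <- switch(kind,
    two_point = rbind(state1 = c(A = 0, B = 10), state2 = c(A = 0, B = -10)),
    dominated = rbind(state1 = c(A = 0, B = 5), state2 = c(A = 2, B = 7)),
    single_state = rbind(state1 = c(A = 1, B = 4)))
  out <- structure(
    list(kind = kind, strategies = colnames(nb), nb = nb,
         weights = rep(1 / nrow(nb), nrow(nb)), evpi = enumerate_evpi(nb)),
    class = "toy_evpi_scenario")
  stopifnot(out$evpi >= 0)
  out
}

#' @export
print.toy_evpi_scenario <- function(x, ...) {
  cat(sprintf("Toy EVPI scenario '%s' (%d states, analytic EVPI = %g)\n",
              x$kind, nrow(x$nb), x$evpi))
  print(x$nb)
  invisible(x)
}
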