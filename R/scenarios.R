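#' Deterministic one-way scenario analysis
#'
#' Re-evaluates the base-case decision model with one parameter overridden
#' at a time, in the layout of a published one-way sensitivity table:
#' scenario name, cohort incremental cost, cohort QALY gain, ICER per
#' QALY, and the probability of cost-effectiveness at the 3x GDP threshold
#' from a PSA re-run with the override held fixed.
#'
#' Recognized override keys: `u_pneumothorax`, `u_post_recovery`,
#' `d_recurrence_days`, `d_initial_days`, `cost_multiplier`,
#' `annual_rate`.
#'
#' @param base A [psa_base_inputs()] bundle.
#' @param scenarios Named list of override lists, e.g.
#'   `list("Utility 0.5" = list(u_pneumothorax = 0.5))`; an empty override
#'   reproduces the base case.
#' @param psa A [psa_config()] used for the per-scenario acceptability
#'   probability; `NULL` skips it (faster, `ce_probability` = `NA`).
#' @return Tibble: `scenario`, `delta_cost`, `delta_qaly`,
#'   `icer_per_qaly`, `ce_probability`.
#' @export
#' @examples
#' base <- psa_base_inputs(17813, 33, two_by_two(4, 33, 16, 33))
#' one_way_scenarios(base, list(base_case = list()))
one_way_scenarios <- function(base, scenarios, psa = NULL) {
  stopifnot(inherits(base, "psa_base"))
  allowed <- c(
    "u_pneumothorax", "u_post_recovery", "d_recurrence_days",
    "d_initial_days", "cost_multiplier", "annual_rate"
  )
  purrr::imap_dfr(scenarios, function(ov, name) {
    bad <- setdiff(names(ov), allowed)
    if (length(bad) > 0) {
      stop_config(
        "unknown override key(s) in scenario '%s': %s",
        name, paste(bad, collapse = ", ")
      )
    }
    b <- apply_overrides(base, ov)
    cea <- scenario_cea(b)
    prob <- NA_real_
    if (!is.null(psa)) {
      prob <- run_psa(b, psa)$prob_ce_at[["gdp3"]]
    }
    tibble::tibble(
      scenario = name,
      delta_cost = cea$delta_cost_cohort,
      delta_qaly = cea$delta_qaly_cohort,
      icer_per_qaly = cea$icer_per_qaly,
      ce_probability = prob
    )
  })
}

apply_overrides <- function(base, ov) {
  b <- base
  if (!is.null(ov$u_pneumothorax) || !is.null(ov$u_post_recovery)) {
    b$utilities <- utility_set(
      u_stable = base$utilities$u_stable,
      u_pneumothorax = ov$u_pneumothorax %||% base$utilities$u_pneumothorax,
      u_post_recovery = ov$u_post_recovery %||% base$utilities$u_post_recovery
    )
  }
  if (!is.null(ov$d_recurrence_days) || !is.null(ov$d_initial_days)) {
    b$episodes <- episode_spec(
      d_initial_days = ov$d_initial_days %||% base$episodes$d_initial_days,
      d_recurrence_days = ov$d_recurrence_days %||% base$episodes$d_recurrence_days
    )
  }
  if (!is.null(ov$annual_rate)) b$discount <- discount_spec(ov$annual_rate)
  if (!is.null(ov$cost_multiplier)) {
    b$cost_multiplier <- base$cost_multiplier * ov$cost_multiplier
  }
  b
}

scenario_cea <- function(b) {
  t <- b$two_by_two
  dq <- delta_qaly_model(
    b, b$utilities$u_pneumothorax, b$utilities$u_post_recovery,
    t$events_treated / t$n_treated, t$events_control / t$n_control
  )
  compute_cea(
    b$delta_cost_per_patient * b$cost_multiplier, b$n_pairs, t, dq,
    gdp_per_capita = b$gdp_per_capita
  )
}

#' Standard one-way scenario grid
#'
#' The conventional grid: base case; pneumothorax utility 0.5 and 0.8;
#' recurrence duration 7 and 21 days; cost +/- 20%; discount rates 0%, 3%
#' and 6%.
#'
#' @return Named override list for [one_way_scenarios()].
#' @export
default_scenarios <- function() {
  list(
    "Base case" = list(),
    "Pneumothorax utility 0.5" = list(u_pneumothorax = 0.5),
    "Pneumothorax utility 0.8" = list(u_pneumothorax = 0.8),
    "Recurrence duration 7 days" = list(d_recurrence_days = 7),
    "Recurrence duration 21 days" = list(d_recurrence_days = 21),
    "Cost +20%" = list(cost_multiplier = 1.2),
    "Cost -20%" = list(cost_multiplier = 0.8),
    "Discount 0%" = list(annual_rate = 0),
    "Discount 3%" = list(annual_rate = 0.03),
    "Discount 6%" = list(annual_rate = 0.06)
  )
}
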