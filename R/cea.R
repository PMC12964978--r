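#' Health-state utilities, episode durations and discounting
#'
#' Parameter bundles for the QALY accrual model. Utilities: stable health
#' 1.0, active pneumothorax episode 0.7, post-recovery after a recurrence
#' 0.95. Episode durations are in days (default 14 for both the initial
#' presentation and a recurrence). Discounting is continuous-time with
#' instantaneous rate `rho = log(1 + annual_rate)`; 0%, 3% and 6% are the
#' usual scenario values.
#'
#' @param u_stable,u_pneumothorax,u_post_recovery Utilities in \[0, 1\].
#' @return `utility_set()`, `episode_spec()`, `discount_spec()`: validated
#'   parameter lists.
#' @export
#' @examples
#' qaly_trajectory(FALSE, NULL, utility_set(), episode_spec(), discount_spec(0))
utility_set <- function(u_stable = 1.0, u_pneumothorax = 0.7,
                        u_post_recovery = 0.95) {
  u <- c(u_stable, u_pneumothorax, u_post_recovery)
  if (any(u < 0 | u > 1)) stop_config("utilities must lie in [0, 1]")
  structure(
    list(
      u_stable = u_stable, u_pneumothorax = u_pneumothorax,
      u_post_recovery = u_post_recovery
    ),
    class = "utility_set"
  )
}

#' @param d_initial_days,d_recurrence_days Episode durations in days.
#' @rdname utility_set
#' @export
episode_spec <- function(d_initial_days = 14, d_recurrence_days = 14) {
  if (d_initial_days <= 0 || d_recurrence_days <= 0) {
    stop_config("episode durations must be positive")
  }
  if (d_initial_days >= 60 * 365 / 12 || d_recurrence_days >= 60 * 365 / 12) {
    stop_config("episode durations must be shorter than the horizon")
  }
  structure(
    list(d_initial_days = d_initial_days, d_recurrence_days = d_recurrence_days),
    class = "episode_spec"
  )
}

#' @param annual_rate Annual discount rate, `0 <= annual_rate < 1`.
#' @rdname utility_set
#' @export
discount_spec <- function(annual_rate = 0.03) {
  if (annual_rate < 0 || annual_rate >= 1) {
    stop_config("annual discount rate must lie in [0, 1)")
  }
  structure(list(annual_rate = annual_rate), class = "discount_spec")
}

# Discounted integral of a constant utility over [a, b] years:
# u * (exp(-rho a) - exp(-rho b)) / rho, continuous limit u * (b - a) at rho 0.
segment_qaly <- function(u, a, b, rho) {
  if (b <= a) return(0)
  if (rho == 0) u * (b - a) else u * (exp(-rho * a) - exp(-rho * b)) / rho
}

# Annual-cycle variant: the year-y slice is weighted by (1 + r)^(-y).
segment_qaly_annual <- function(u, a, b, annual_rate) {
  if (b <= a) return(0)
  years <- seq(floor(a), ceiling(b) - 1)
  slices <- vapply(years, function(y) {
    (min(b, y + 1) - max(a, y)) * (1 + annual_rate)^(-y)
  }, numeric(1))
  u * sum(slices)
}

#' QALYs accrued over the follow-up horizon for one patient
#'
#' Integrates a piecewise-constant utility path against a discount factor
#' over the 60-month horizon. The path starts in the pneumothorax state for
#' the initial episode, then returns to stable health. On recurrence at
#' `t_recurrence_months` the patient re-enters the pneumothorax state for
#' the recurrence duration and then remains at the post-recovery utility
#' to the horizon. Patients who never recur stay at the stable utility.
#' Default discounting is the continuous form `int u(t) exp(-rho t) dt`
#' with `rho = log(1 + annual_rate)` and `t` in years; `accrual =
#' "annual_cycle"` instead weights each year-`y` slice by `(1+r)^-y`.
#'
#' Episodes extending past the horizon are truncated there (flagged in the
#' `truncated` attribute).
#'
#' @param recurrence Logical: did this patient recur?
#' @param t_recurrence_months Recurrence time in months (required when
#'   `recurrence` is `TRUE`; must lie strictly inside the horizon).
#' @param utilities A [utility_set()].
#' @param episodes An [episode_spec()].
#' @param discount A [discount_spec()].
#' @param horizon_months Follow-up horizon (60).
#' @param accrual `"continuous"` or `"annual_cycle"`.
#' @return QALYs (scalar, years of perfect health equivalent).
#' @export
qaly_trajectory <- function(recurrence, t_recurrence_months = NULL,
                            utilities = utility_set(),
                            episodes = episode_spec(),
                            discount = discount_spec(0),
                            horizon_months = 60,
                            accrual = c("continuous", "annual_cycle")) {
  accrual <- match.arg(accrual)
  horizon <- horizon_months / 12
  d_init <- episodes$d_initial_days / 365
  d_rec <- episodes$d_recurrence_days / 365
  rho <- log(1 + discount$annual_rate)
  seg <- if (accrual == "continuous") {
    function(u, a, b) segment_qaly(u, a, b, rho)
  } else {
    function(u, a, b) segment_qaly_annual(u, a, b, discount$annual_rate)
  }

  truncated <- FALSE
  if (recurrence) {
    if (is.null(t_recurrence_months) ||
        t_recurrence_months <= 0 || t_recurrence_months >= horizon_months) {
      stop_input("recurrence time must lie strictly inside (0, horizon) months")
    }
    t_rec <- t_recurrence_months / 12
    rec_end <- t_rec + d_rec
    if (rec_end > horizon) {
      rec_end <- horizon
      truncated <- TRUE
    }
    # the initial episode may itself overlap an early recurrence
    init_end <- min(d_init, t_rec)
    total <- seg(utilities$u_pneumothorax, 0, init_end) +
      seg(utilities$u_stable, init_end, t_rec) +
      seg(utilities$u_pneumothorax, t_rec, rec_end) +
      seg(utilities$u_post_recovery, rec_end, horizon)
  } else {
    init_end <- min(d_init, horizon)
    total <- seg(utilities$u_pneumothorax, 0, init_end) +
      seg(utilities$u_stable, init_end, horizon)
  }
  structure(total, truncated = truncated)
}

#' Per-arm QALYs and recurrence counts for a matched cohort
#'
#' Sums [qaly_trajectory()] over patients in each arm using each patient's
#' recurrence indicator and time.
#'
#' @param matched Matched cohort tibble (equal arm sizes; see
#'   [matched_cohort()]).
#' @inheritParams qaly_trajectory
#' @return Tibble with one row per arm: `arm`, `n`, `qalys`, `recurrences`.
#' @export
cohort_effects <- function(matched, utilities = utility_set(),
                           episodes = episode_spec(),
                           discount = discount_spec(0),
                           horizon_months = 60,
                           accrual = "continuous") {
  matched <- check_cohort(matched)
  n_by_arm <- table(matched$arm)
  if (length(n_by_arm) != 2 || n_by_arm[1] != n_by_arm[2]) {
    stop_input("matched cohort must have two equal-sized arms")
  }
  per_patient <- purrr::map2_dbl(
    matched$recurrence == 1, matched$time_months,
    function(rec, t) {
      qaly_trajectory(
        rec, if (rec) t else NULL, utilities, episodes, discount,
        horizon_months, accrual
      )
    }
  )
  dplyr::summarise(
    dplyr::group_by(dplyr::mutate(matched, .qaly = per_patient), .data$arm),
    n = dplyr::n(), qalys = sum(.data$.qaly),
    recurrences = sum(.data$recurrence), .groups = "drop"
  )
}

#' Incremental cost-effectiveness results
#'
#' Combines the per-patient incremental cost, the matched recurrence 2x2
#' table and the cohort QALY gain into the decision metrics: cohort
#' incremental cost, ICER per QALY gained, ICER per recurrence avoided
#' (incremental cost per patient divided by the absolute risk reduction),
#' NNT, and cost-effectiveness verdicts against the 1x and 3x
#' GDP-per-capita willingness-to-pay thresholds.
#'
#' @param delta_cost_per_patient Incremental cost of VATS per patient (CNY).
#' @param n_pairs Number of matched pairs.
#' @param two_by_two Recurrence counts, a [two_by_two()].
#' @param delta_qaly Cohort QALY gain of VATS.
#' @param gdp_per_capita GDP per capita (CNY); thresholds are 1x and 3x.
#' @param arr_digits Optional rounding of the ARR before the
#'   per-recurrence ICER (e.g. 3 reproduces published rounded-ARR
#'   arithmetic); `NULL` uses full precision.
#' @return A `cea_result` tibble (one row) with a `wtp_thresholds`
#'   attribute.
#' @export
#' @examples
#' compute_cea(17813, 33, two_by_two(4, 33, 16, 33), 3.67, arr_digits = 3)
compute_cea <- function(delta_cost_per_patient, n_pairs, two_by_two,
                        delta_qaly, gdp_per_capita = 95749,
                        arr_digits = NULL) {
  if (n_pairs <= 0) stop_input("n_pairs must be positive")
  eff <- effect_summary(two_by_two)
  arr <- eff$arr
  arr_used <- if (is.null(arr_digits)) arr else round(arr, arr_digits)
  delta_cost_cohort <- delta_cost_per_patient * n_pairs

  icer_qaly <- if (delta_qaly == 0) {
    NA_real_
  } else {
    delta_cost_cohort / delta_qaly
  }
  dominant <- !is.na(icer_qaly) && delta_cost_cohort < 0 && delta_qaly > 0
  icer_rec <- if (arr_used > 0) delta_cost_per_patient / arr_used else NA_real_

  thresholds <- c(gdp1 = gdp_per_capita, gdp3 = 3 * gdp_per_capita)
  out <- tibble::tibble(
    delta_cost_per_patient = delta_cost_per_patient,
    delta_cost_cohort = delta_cost_cohort,
    delta_qaly_cohort = delta_qaly,
    arr = arr,
    arr_used = arr_used,
    recurrences_avoided = arr * n_pairs,
    nnt = eff$nnt,
    icer_per_qaly = icer_qaly,
    icer_per_recurrence = icer_rec,
    dominant = dominant,
    cost_effective_1x = !is.na(icer_qaly) &&
      (dominant || icer_qaly <= thresholds[["gdp1"]]),
    cost_effective_3x = !is.na(icer_qaly) &&
      (dominant || icer_qaly <= thresholds[["gdp3"]])
  )
  class(out) <- c("cea_result", class(out))
  attr(out, "wtp_thresholds") <- thresholds
  out
}

#' @rdname tidy.propensity_fit
#' @exportS3Method generics::tidy
tidy.cea_result <- function(x, ...) {
  tibble::tibble(
    metric = c(
      "delta_cost_per_patient", "delta_cost_cohort", "delta_qaly_cohort",
      "recurrences_avoided_per_patient", "nnt", "icer_per_qaly",
      "icer_per_recurrence", "wtp_1x_gdp", "wtp_3x_gdp"
    ),
    value = c(
      x$delta_cost_per_patient, x$delta_cost_cohort, x$delta_qaly_cohort,
      x$arr, x$nnt, x$icer_per_qaly, x$icer_per_recurrence,
      attr(x, "wtp_thresholds")[["gdp1"]], attr(x, "wtp_thresholds")[["gdp3"]]
    )
  )
}

#' @rdname tidy.propensity_fit
#' @exportS3Method generics::glance
glance.cea_result <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "icer_per_qaly", "icer_per_recurrence", "dominant",
    "cost_effective_1x", "cost_effective_3x"
  )]
}

#' Render a cost-effectiveness summary table as CSV
#'
#' Metric/value layout; utility, duration and threshold settings are
#' embedded as `# key: value` comment lines above the header.
#'
#' @param cea A `cea_result`.
#' @param path Output path.
#' @param utilities,episodes A [utility_set()] and [episode_spec()] for the
#'   metadata block.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(cea, path, utilities = utility_set(),
                          episodes = episode_spec()) {
  meta <- c(
    sprintf("# u_stable: %g", utilities$u_stable),
    sprintf("# u_pneumothorax: %g", utilities$u_pneumothorax),
    sprintf("# u_post_recovery: %g", utilities$u_post_recovery),
    sprintf("# d_initial_days: %g", episodes$d_initial_days),
    sprintf("# d_recurrence_days: %g", episodes$d_recurrence_days),
    sprintf("# wtp_1x: %g", attr(cea, "wtp_thresholds")[["gdp1"]]),
    sprintf("# wtp_3x: %g", attr(cea, "wtp_thresholds")[["gdp3"]])
  )
  writeLines(meta, path)
  readr::write_csv(generics::tidy(cea), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
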