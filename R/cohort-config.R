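#' Default covariate marginals calibrated to the pre-matching cohort
#'
#' Per-arm category probabilities for the seven baseline covariates of a
#' first-episode primary spontaneous pneumothorax cohort with CT-confirmed
#' blebs, expressed as exact count fractions from the published baseline
#' table (chest tube n = 57, VATS n = 188). Each element is a named list
#' with one probability vector per arm; vectors are ordered as the category
#' levels documented in [generate_cohort()].
#'
#' @return Named list of per-covariate, per-arm probability vectors.
#' @export
default_marginals <- function() {
  list(
    sex = list( # male, female
      vats = c(161, 27) / 188,
      chest_tube = c(46, 11) / 57
    ),
    age_ge45 = list( # <45, >=45
      vats = c(161, 27) / 188,
      chest_tube = c(21, 36) / 57
    ),
    smoker = list( # no, yes
      vats = c(136, 52) / 188,
      chest_tube = c(23, 34) / 57
    ),
    laterality = list( # left, right
      vats = c(83, 105) / 188,
      chest_tube = c(22, 35) / 57
    ),
    collapse_cat = list( # 30-50%, >50%
      vats = c(93, 95) / 188,
      chest_tube = c(26, 31) / 57
    ),
    bleb_diam_cat = list( # <1cm, 1-5cm, >5cm
      vats = c(127, 59, 2) / 188,
      chest_tube = c(10, 36, 11) / 57
    ),
    bleb_count_cat = list( # 1-2, 3-5, >5
      vats = c(163, 20, 5) / 188,
      chest_tube = c(19, 21, 17) / 57
    )
  )
}

covariate_levels <- function() {
  list(
    sex = c("male", "female"),
    age_ge45 = c("0", "1"),
    smoker = c("0", "1"),
    laterality = c("left", "right"),
    collapse_cat = c("c30_50", "gt50"),
    bleb_diam_cat = c("lt1cm", "cm1_5", "gt5cm"),
    bleb_count_cat = c("n1_2", "n3_5", "gt5")
  )
}

#' Configure a synthetic pneumothorax cohort
#'
#' Defines the generating model for [generate_cohort()]: per-arm covariate
#' marginals with a confounding dial, an exponential proportional-hazards
#' recurrence law administratively censored at 60 months, and per-arm
#' log-normal cost and length-of-stay laws. Defaults reproduce the study
#' conditions: pre-matching marginals of the published baseline table, a
#' chest-tube monthly recurrence hazard giving 45.6% five-year recurrence,
#' a treatment hazard ratio of 0.166, and cost medians/IQRs matching the
#' printed post-match values (chest tube ¥6,256, VATS ¥26,922).
#'
#' The confounding dial works per covariate category: the two arms sample
#' from probability vectors `softmax(log g +/- m/2 * delta)` where `g` is
#' the (normalized) geometric mean of the configured per-arm marginals,
#' `delta` their per-category log-ratio, and `m = confounding_multiplier`.
#' At `m = 1` each arm reproduces its configured marginal exactly; at
#' `m = 0` the arms are exchangeable (no confounding); larger `m` is more
#' confounded.
#'
#' @param n_per_arm Number of patients per treatment arm.
#' @param covariate_marginals Per-covariate, per-arm category probabilities;
#'   see [default_marginals()] for structure and category order.
#' @param confounding_multiplier Scalar dial `m` on the covariate-arm
#'   association (0 = none, 1 = as configured).
#' @param baseline_hazard_monthly Constant monthly recurrence hazard in the
#'   chest-tube arm.
#' @param true_log_hr Log hazard ratio of VATS versus chest tube.
#' @param horizon_months Administrative censoring horizon; fixed at 60.
#' @param cost_meanlog,cost_sdlog Named numeric vectors (`vats`,
#'   `chest_tube`) of log-normal cost parameters (CNY).
#' @param los_meanlog,los_sdlog Same structure for length of stay (days).
#' @param recurrence_cost_cny Extra management cost added to a chest-tube
#'   patient's total when recurrence occurs.
#' @param p_complication Named per-arm probability of any complication.
#' @param p_pal_chest_tube Probability of prolonged air leak (> 5 days) in
#'   the chest-tube arm (a subset of complications).
#' @param crossover_prob_given_pal Probability that a chest-tube patient
#'   with prolonged air leak crosses over to rescue VATS (cost attribution
#'   only; the intention-to-treat arm never changes).
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   cohort.
#'
#' @return A `cohort_config` list, validated.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_arm = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_per_arm = 500,
                          covariate_marginals = default_marginals(),
                          confounding_multiplier = 1,
                          baseline_hazard_monthly = -log(1 - 26 / 57) / 60,
                          true_log_hr = log(0.166),
                          horizon_months = 60,
                          cost_meanlog = c(vats = log(26922), chest_tube = log(6256)),
                          cost_sdlog = c(
                            vats = log(33206 / 23455) / (2 * qnorm(0.75)),
                            chest_tube = log(9306 / 3769) / (2 * qnorm(0.75))
                          ),
                          los_meanlog = c(vats = log(8), chest_tube = log(7)),
                          los_sdlog = c(
                            vats = log(10.5 / 7) / (2 * qnorm(0.75)),
                            chest_tube = log(10.5 / 4) / (2 * qnorm(0.75))
                          ),
                          recurrence_cost_cny = 5000,
                          p_complication = c(vats = 47 / 188, chest_tube = 20 / 57),
                          p_pal_chest_tube = 6 / 57,
                          crossover_prob_given_pal = 0.6,
                          seed = 1L) {
  cfg <- list(
    n_per_arm = as.integer(n_per_arm),
    covariate_marginals = covariate_marginals,
    confounding_multiplier = confounding_multiplier,
    baseline_hazard_monthly = baseline_hazard_monthly,
    true_log_hr = true_log_hr,
    horizon_months = horizon_months,
    cost_meanlog = cost_meanlog,
    cost_sdlog = cost_sdlog,
    los_meanlog = los_meanlog,
    los_sdlog = los_sdlog,
    recurrence_cost_cny = recurrence_cost_cny,
    p_complication = p_complication,
    p_pal_chest_tube = p_pal_chest_tube,
    crossover_prob_given_pal = crossover_prob_given_pal,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_per_arm < 1) stop_config("n_per_arm must be >= 1")
  if (cfg$horizon_months != 60) stop_config("horizon_months is fixed at 60")
  if (cfg$baseline_hazard_monthly <= 0) {
    stop_config("baseline_hazard_monthly must be positive")
  }
  lv <- covariate_levels()
  for (cov in names(lv)) {
    m <- cfg$covariate_marginals[[cov]]
    if (is.null(m)) stop_config("missing marginals for covariate '%s'", cov)
    for (arm in c("vats", "chest_tube")) {
      p <- m[[arm]]
      if (length(p) != length(lv[[cov]]) || any(p <= 0) ||
          abs(sum(p) - 1) > 1e-12) {
        stop_config(
          "invalid probability vector for covariate '%s' (arm %s): must be positive and sum to 1",
          cov, arm
        )
      }
    }
  }
  for (fld in c("cost_meanlog", "cost_sdlog", "los_meanlog", "los_sdlog")) {
    if (!all(c("vats", "chest_tube") %in% names(cfg[[fld]]))) {
      stop_config("%s must be named with 'vats' and 'chest_tube'", fld)
    }
  }
  probs <- c(cfg$p_complication, cfg$p_pal_chest_tube, cfg$crossover_prob_given_pal)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must lie in [0, 1]")
  cfg
}

# Arm-specific category probabilities after applying the confounding dial.
dialed_marginal <- function(p_vats, p_chest, multiplier) {
  g <- sqrt(p_vats * p_chest)
  delta <- log(p_vats / p_chest)
  pv <- g * exp(multiplier * delta / 2)
  pc <- g * exp(-multiplier * delta / 2)
  list(vats = pv / sum(pv), chest_tube = pc / sum(pc))
}
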