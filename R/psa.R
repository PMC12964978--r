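#' Configure the probabilistic sensitivity analysis
#'
#' Parameter distributions for Monte Carlo propagation of uncertainty.
#' Utilities and probabilities are beta (method of moments from mean and
#' SE), costs gamma (shape/scale moment matching). A distribution with
#' `se = 0` is degenerate: every draw equals the mean. Each parameter owns
#' a named random substream derived from the seed, so adding a parameter
#' never perturbs the draws of the others.
#'
#' Defaults follow standard practice where the study's own distributional
#' appendix is not available: utilities beta with SE = 10% of the mean,
#' incremental cost gamma with SE = 20% of the mean, per-arm recurrence
#' probabilities beta with shapes (events + 1, non-events + 1).
#'
#' @param n_iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed.
#' @param distributions Named list of `list(dist =, mean =, se =)` or
#'   `list(dist = "beta_counts", events =, nonevents =)` entries;
#'   `dist` one of `"beta"`, `"gamma"`, `"beta_counts"`.
#' @param wtp_grid Ascending willingness-to-pay grid (CNY/QALY) including
#'   the 1x and 3x GDP-per-capita thresholds.
#' @return A `psa_config` list, validated.
#' @export
psa_config <- function(n_iterations = 10000, seed = 1L,
                       distributions = NULL,
                       wtp_grid = c(
                         seq(0, 400000, by = 10000), 95749, 287247
                       )) {
  wtp_grid <- sort(unique(wtp_grid))
  if (length(wtp_grid) == 0) stop_config("wtp_grid must be non-empty")
  if (n_iterations < 1) stop_config("n_iterations must be >= 1")
  cfg <- structure(
    list(
      n_iterations = as.integer(n_iterations), seed = as.integer(seed),
      distributions = distributions, wtp_grid = wtp_grid
    ),
    class = "psa_config"
  )
  for (nm in names(distributions)) validate_dist(distributions[[nm]], nm)
  cfg
}

validate_dist <- function(d, name) {
  if (is.null(d$dist)) stop_config("distribution '%s' has no dist field", name)
  if (d$dist == "beta_counts") {
    if (d$events < 0 || d$nonevents < 0) {
      stop_config("distribution '%s': counts must be non-negative", name)
    }
    return(invisible(TRUE))
  }
  if (is.null(d$mean) || is.null(d$se) || d$se < 0) {
    stop_config("distribution '%s' needs a mean and a non-negative se", name)
  }
  if (d$dist == "beta") {
    if (d$mean <= 0 || d$mean >= 1) {
      stop_config("distribution '%s': beta mean must lie in (0, 1)", name)
    }
    if (d$se > 0 && d$se^2 >= d$mean * (1 - d$mean)) {
      stop_config(
        "distribution '%s': infeasible beta moments (se^2 >= m(1-m))", name
      )
    }
  } else if (d$dist == "gamma") {
    if (d$mean <= 0) stop_config("distribution '%s': gamma mean must be positive", name)
  } else {
    stop_config("distribution '%s': unknown dist '%s'", name, d$dist)
  }
  invisible(TRUE)
}

#' Draw all iterations of one PSA parameter
#'
#' Reproducible: the draws depend only on (`seed`, parameter name,
#' `n_iterations`). Beta shapes from mean `m` and SE `s`:
#' `v = m(1-m)/s^2 - 1`, `alpha = m v`, `beta = (1-m) v`. Gamma shape
#' `(m/s)^2`, scale `s^2/m`.
#'
#' @param config A [psa_config()].
#' @param name Parameter name (keys `config$distributions`).
#' @return Numeric vector of length `n_iterations`.
#' @export
draw_parameters <- function(config, name) {
  d <- config$distributions[[name]]
  if (is.null(d)) stop_config("no distribution named '%s'", name)
  validate_dist(d, name)
  n <- config$n_iterations
  with_seed(derive_seed(config$seed, name), {
    if (d$dist == "beta_counts") {
      rbeta(n, d$events + 1, d$nonevents + 1)
    } else if (d$se == 0) {
      rep(d$mean, n)
    } else if (d$dist == "beta") {
      v <- d$mean * (1 - d$mean) / d$se^2 - 1
      rbeta(n, d$mean * v, (1 - d$mean) * v)
    } else {
      rgamma(n, shape = (d$mean / d$se)^2, scale = d$se^2 / d$mean)
    }
  })
}

#' Default PSA distributions for a matched-cohort base case
#'
#' @param base A `psa_base` list from [psa_base_inputs()].
#' @param cost_se_frac,utility_se_frac SE as a fraction of the mean for the
#'   cost and utility parameters.
#' @return Named distribution list for [psa_config()].
#' @export
default_psa_distributions <- function(base, cost_se_frac = 0.2,
                                      utility_se_frac = 0.1) {
  t <- base$two_by_two
  list(
    delta_cost_per_patient = list(
      dist = "gamma", mean = base$delta_cost_per_patient,
      se = cost_se_frac * base$delta_cost_per_patient
    ),
    u_pneumothorax = list(
      dist = "beta", mean = base$utilities$u_pneumothorax,
      se = utility_se_frac * base$utilities$u_pneumothorax
    ),
    u_post_recovery = list(
      dist = "beta", mean = base$utilities$u_post_recovery,
      se = utility_se_frac * base$utilities$u_post_recovery
    ),
    p_rec_treated = list(
      dist = "beta_counts", events = t$events_treated,
      nonevents = t$n_treated - t$events_treated
    ),
    p_rec_control = list(
      dist = "beta_counts", events = t$events_control,
      nonevents = t$n_control - t$events_control
    )
  )
}

#' Base-case inputs for the PSA and scenario engines
#'
#' Bundles the deterministic base case: matched-pair count, recurrence
#' 2x2 table, per-patient incremental cost, utilities/episodes/discount,
#' the representative recurrence time used for QALY accrual, and the
#' GDP-per-capita threshold anchor.
#'
#' @param delta_cost_per_patient Per-patient incremental cost (CNY).
#' @param n_pairs Matched pairs.
#' @param two_by_two A [two_by_two()] of recurrences.
#' @param utilities,episodes,discount Parameter bundles (see
#'   [utility_set()]).
#' @param t_recurrence_months Representative recurrence time used when
#'   integrating the recurrence utility path.
#' @param horizon_months Follow-up horizon.
#' @param gdp_per_capita WTP anchor (CNY).
#' @param cost_multiplier Deterministic scaling of the incremental cost
#'   (scenario engine).
#' @return A `psa_base` list.
#' @export
psa_base_inputs <- function(delta_cost_per_patient, n_pairs, two_by_two,
                            utilities = utility_set(),
                            episodes = episode_spec(),
                            discount = discount_spec(0),
                            t_recurrence_months = 15,
                            horizon_months = 60,
                            gdp_per_capita = 95749,
                            cost_multiplier = 1) {
  structure(
    list(
      delta_cost_per_patient = delta_cost_per_patient,
      n_pairs = n_pairs, two_by_two = two_by_two,
      utilities = utilities, episodes = episodes, discount = discount,
      t_recurrence_months = t_recurrence_months,
      horizon_months = horizon_months,
      gdp_per_capita = gdp_per_capita,
      cost_multiplier = cost_multiplier
    ),
    class = "psa_base"
  )
}

# Cohort QALY gain for given parameter values: n_pairs * (p_ctrl - p_trt) *
# (QALY without recurrence - QALY with recurrence at the representative time).
delta_qaly_model <- function(base, u_pneu, u_post, p_trt, p_ctrl) {
  utils_i <- utility_set(
    u_stable = base$utilities$u_stable,
    u_pneumothorax = u_pneu, u_post_recovery = u_post
  )
  q_norec <- qaly_trajectory(
    FALSE, NULL, utils_i, base$episodes, base$discount, base$horizon_months
  )
  q_rec <- qaly_trajectory(
    TRUE, base$t_recurrence_months, utils_i, base$episodes, base$discount,
    base$horizon_months
  )
  base$n_pairs * (p_ctrl - p_trt) * (as.numeric(q_norec) - as.numeric(q_rec))
}

#' Run the probabilistic sensitivity analysis
#'
#' Recomputes the cohort incremental cost and QALY gain through the
#' decision model for each drawn parameter set, classifies each iteration
#' on the cost-effectiveness plane (NE/NW/SE/SW by the signs of the
#' incremental effect and cost), and evaluates the acceptability curve on
#' the configured WTP grid. Iterations producing non-finite values are
#' excluded from the curve and counted in `n_faulted`.
#'
#' @param base A [psa_base_inputs()] bundle.
#' @param config A [psa_config()]; when `config$distributions` is `NULL`,
#'   [default_psa_distributions()] is used.
#' @return A `psa_result`: `draws` tibble (`iteration`, `delta_cost`,
#'   `delta_qaly`, `quadrant`, `faulted`), `quadrant_counts`, `ceac`
#'   tibble, `prob_ce_at` named thresholds, `n_faulted`, `base_cea`.
#' @export
#' @examples
#' base <- psa_base_inputs(17813, 33, two_by_two(4, 33, 16, 33))
#' psa <- run_psa(base, psa_config(n_iterations = 500, seed = 1))
#' psa$quadrant_counts
run_psa <- function(base, config = psa_config()) {
  stopifnot(inherits(base, "psa_base"))
  if (is.null(config$distributions)) {
    config$distributions <- default_psa_distributions(base)
    for (nm in names(config$distributions)) {
      validate_dist(config$distributions[[nm]], nm)
    }
  }
  n <- config$n_iterations
  dc_pp <- draw_parameters(config, "delta_cost_per_patient") * base$cost_multiplier
  u_pneu <- draw_parameters(config, "u_pneumothorax")
  u_post <- draw_parameters(config, "u_post_recovery")
  p_trt <- draw_parameters(config, "p_rec_treated")
  p_ctrl <- draw_parameters(config, "p_rec_control")

  delta_cost <- dc_pp * base$n_pairs
  delta_qaly <- vapply(seq_len(n), function(i) {
    delta_qaly_model(base, u_pneu[i], u_post[i], p_trt[i], p_ctrl[i])
  }, numeric(1))

  faulted <- !is.finite(delta_cost) | !is.finite(delta_qaly)
  quadrant <- dplyr::case_when(
    faulted ~ NA_character_,
    delta_qaly > 0 & delta_cost > 0 ~ "NE",
    delta_qaly <= 0 & delta_cost > 0 ~ "NW",
    delta_qaly > 0 & delta_cost <= 0 ~ "SE",
    TRUE ~ "SW"
  )
  draws <- tibble::tibble(
    iteration = seq_len(n), delta_cost = delta_cost,
    delta_qaly = delta_qaly, quadrant = quadrant, faulted = faulted
  )
  quadrant_counts <- vapply(
    c(NE = "NE", NW = "NW", SE = "SE", SW = "SW"),
    function(q) sum(quadrant == q, na.rm = TRUE), integer(1)
  )
  ceac_tbl <- ceac_curve(draws, config$wtp_grid)
  named <- c(gdp1 = base$gdp_per_capita, gdp3 = 3 * base$gdp_per_capita)
  prob_ce_at <- vapply(named, function(l) ceac_at(draws, l), numeric(1))

  base_cea <- compute_cea(
    base$delta_cost_per_patient * base$cost_multiplier, base$n_pairs,
    base$two_by_two,
    delta_qaly_model(
      base, base$utilities$u_pneumothorax, base$utilities$u_post_recovery,
      base$two_by_two$events_treated / base$two_by_two$n_treated,
      base$two_by_two$events_control / base$two_by_two$n_control
    ),
    gdp_per_capita = base$gdp_per_capita
  )
  structure(
    list(
      draws = draws, quadrant_counts = quadrant_counts, ceac = ceac_tbl,
      prob_ce_at = prob_ce_at, n_faulted = sum(faulted),
      base_cea = base_cea, config = config
    ),
    class = "psa_result"
  )
}

# P(net monetary benefit > 0) at one threshold; ties count as not
# cost-effective; faulted iterations excluded.
ceac_at <- function(draws, lambda) {
  ok <- !draws$faulted
  if (!any(ok)) return(NA_real_)
  mean(lambda * draws$delta_qaly[ok] - draws$delta_cost[ok] > 0)
}

ceac_curve <- function(draws, wtp_grid) {
  tibble::tibble(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(l) ceac_at(draws, l), numeric(1))
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Probability, at each willingness-to-pay value, that the intervention
#' has positive net monetary benefit `lambda * dQALY - dCost` across the
#' PSA draws (ties counted as not cost-effective).
#'
#' @param result A `psa_result`.
#' @param wtp_grid Ascending WTP values; defaults to the run's grid.
#' @return Tibble (`wtp`, `probability`).
#' @export
ceac <- function(result, wtp_grid = NULL) {
  stopifnot(inherits(result, "psa_result"))
  grid <- wtp_grid %||% result$config$wtp_grid
  if (length(grid) == 0) stop_config("wtp_grid must be non-empty")
  ceac_curve(result$draws, sort(grid))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA: %d iterations (%d faulted); quadrants NE %d / NW %d / SE %d / SW %d\n",
    nrow(x$draws), x$n_faulted,
    x$quadrant_counts[["NE"]], x$quadrant_counts[["NW"]],
    x$quadrant_counts[["SE"]], x$quadrant_counts[["SW"]]
  ))
  cat(sprintf(
    "P(cost-effective): %.4f at 1x GDP, %.4f at 3x GDP\n",
    x$prob_ce_at[["gdp1"]], x$prob_ce_at[["gdp3"]]
  ))
  invisible(x)
}

#' Cost-effectiveness plane and acceptability-curve plots
#'
#' @param result A `psa_result`.
#' @param wtp Reference WTP slope drawn on the plane (CNY/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(result, wtp = NULL) {
  ok <- dplyr::filter(result$draws, !.data$faulted)
  p <- ggplot2::ggplot(ok, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(
      x = "incremental QALYs", y = "incremental cost (CNY)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed")
  }
  p
}

#' @rdname plot_ce_plane
#' @export
plot_ceac <- function(result) {
  ggplot2::ggplot(result$ceac, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "willingness to pay (CNY per QALY)",
      y = "probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' Export PSA data layers as CSV
#'
#' CE-plane draws (`iteration`, `delta_cost`, `delta_qaly`, `quadrant`)
#' and the CEAC (`wtp`, `probability`).
#'
#' @param result A `psa_result`.
#' @param plane_path,ceac_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_psa_csv <- function(result, plane_path, ceac_path) {
  readr::write_csv(
    result$draws[, c("iteration", "delta_cost", "delta_qaly", "quadrant")],
    plane_path
  )
  readr::write_csv(result$ceac, ceac_path)
  invisible(c(plane_path, ceac_path))
}
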