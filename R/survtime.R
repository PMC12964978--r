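#' Kaplan-Meier recurrence-free estimate
#'
#' Product-limit estimator of the recurrence-free function with log-log
#' confidence intervals. The median is the earliest time at which the
#' survival estimate drops to 0.5 or below; when the curve never reaches
#' 0.5 the median is "not reached" (`NA` with `median_reached = FALSE`).
#'
#' @param times Positive event/censoring times (months).
#' @param event_flags 1 = recurrence observed, 0 = censored.
#' @return A `km_fit`: `curve` tibble (`time`, `n_risk`, `n_event`,
#'   `survival`, `lower`, `upper`), `median`, `median_ci`,
#'   `median_reached`, and the underlying `survfit`.
#' @export
#' @examples
#' km_fit(c(1, 2, 3, 4), c(1, 0, 1, 0))$curve
km_fit <- function(times, event_flags) {
  check_surv_input(times, event_flags)
  sf <- survival::survfit(
    survival::Surv(times, event_flags) ~ 1,
    conf.type = "log-log"
  )
  curve <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv, lower = sf$lower, upper = sf$upper
  )
  med <- unname(summary(sf)$table["median"])
  ci <- unname(summary(sf)$table[c("0.95LCL", "0.95UCL")])
  structure(
    list(
      curve = curve,
      median = med,
      median_ci = ci,
      median_reached = !is.na(med),
      survfit = sf
    ),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier fit: %d distinct times, %d events; median %s\n",
    nrow(x$curve), sum(x$curve$n_event),
    if (x$median_reached) sprintf("%.2f months", x$median) else "not reached"
  ))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events under the hypergeometric null at each
#' distinct event time, squared over the variance; one degree of freedom.
#'
#' @param times_a,flags_a,times_b,flags_b Times and event flags per group.
#' @return One-row tibble (`statistic`, `p_value`, `n_events`).
#' @export
logrank_test <- function(times_a, flags_a, times_b, flags_b) {
  check_surv_input(times_a, flags_a)
  check_surv_input(times_b, flags_b)
  if (sum(flags_a) + sum(flags_b) == 0) {
    stop_input("log-rank test requires at least one event")
  }
  grp <- c(rep("a", length(times_a)), rep("b", length(times_b)))
  sd <- survival::survdiff(
    survival::Surv(c(times_a, times_b), c(flags_a, flags_b)) ~ grp
  )
  tibble::tibble(
    statistic = sd$chisq,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n_events = sum(sd$obs)
  )
}

#' Cox proportional-hazards fit for the treatment effect
#'
#' One-covariate Cox partial-likelihood fit of the group indicator
#' (treated = 1), Breslow tie handling by default (Efron selectable),
#' standard error from the observed information.
#'
#' @param times Event/censoring times.
#' @param event_flags 1 = event, 0 = censored.
#' @param group_indicator 0/1 treatment indicator.
#' @param ties_method `"breslow"` or `"efron"`.
#' @return A `cox_fit`: `log_hr`, `se`, `hr`, `ci95` (exp of
#'   `log_hr -/+ 1.96 se`), `ties_method`, underlying `coxph`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_arm = 300, seed = 11))
#' cox_fit(cohort$time_months, cohort$recurrence, cohort$arm == "vats")
cox_fit <- function(times, event_flags, group_indicator,
                    ties_method = c("breslow", "efron")) {
  ties_method <- match.arg(ties_method)
  check_surv_input(times, event_flags)
  g <- as.numeric(group_indicator)
  if (length(unique(g)) < 2) stop_input("both groups must be present")
  if (sum(event_flags) == 0) stop_input("Cox fit requires at least one event")
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(times, event_flags) ~ g,
    ties = ties_method,
    control = survival::coxph.control(eps = 1e-9, iter.max = 100)
  ))
  beta <- unname(coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    abort(
      sprintf(
        "monotone partial likelihood: log HR estimate diverges (beta = %.3g, events treated = %d, control = %d)",
        beta, sum(event_flags[g == 1]), sum(event_flags[g == 0])
      ),
      class = "pneumocea_divergence_error"
    )
  }
  structure(
    list(
      log_hr = beta, se = se, hr = exp(beta),
      ci95 = exp(beta + c(-1, 1) * qnorm(0.975) * se),
      ties_method = ties_method, coxph = fit
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox fit (%s ties): HR %.3f (95%% CI %.3f-%.3f), log HR %.4f (SE %.4f)\n",
    x$ties_method, x$hr, x$ci95[1], x$ci95[2], x$log_hr, x$se
  ))
  invisible(x)
}

#' @rdname tidy.propensity_fit
#' @exportS3Method generics::tidy
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = "treated", estimate = x$log_hr, std.error = x$se,
    hr = x$hr, conf.low = x$ci95[1], conf.high = x$ci95[2],
    p.value = 2 * pnorm(-abs(x$log_hr / x$se))
  )
}

#' Rank tests for cost and length-of-stay comparisons
#'
#' Unpaired mode: Mann-Whitney U with normal approximation and tie
#' correction (the U statistic reported for the first sample). Paired
#' mode: Wilcoxon signed-rank with zero differences dropped. When every
#' paired difference is zero the result is degenerate with p = 1.
#'
#' @param sample_a,sample_b Numeric samples (equal length when paired).
#' @param paired Logical.
#' @return One-row tibble (`statistic`, `p_value`, `method`, `degenerate`).
#' @export
rank_tests <- function(sample_a, sample_b, paired = FALSE) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop_input("samples must be non-empty")
  }
  if (paired) {
    if (length(sample_a) != length(sample_b)) {
      stop_input("paired samples must have equal length")
    }
    if (all(sample_a == sample_b)) {
      return(tibble::tibble(
        statistic = NA_real_, p_value = 1,
        method = "wilcoxon_signed_rank", degenerate = TRUE
      ))
    }
    wt <- suppressWarnings(
      wilcox.test(sample_a, sample_b, paired = TRUE, exact = FALSE, correct = TRUE)
    )
    tibble::tibble(
      statistic = unname(wt$statistic), p_value = wt$p.value,
      method = "wilcoxon_signed_rank", degenerate = FALSE
    )
  } else {
    wt <- suppressWarnings(
      wilcox.test(sample_a, sample_b, exact = FALSE, correct = TRUE)
    )
    tibble::tibble(
      statistic = unname(wt$statistic), p_value = wt$p.value,
      method = "mann_whitney_u", degenerate = FALSE
    )
  }
}

#' Per-arm KM curves as plot-ready data
#'
#' @param cohort Cohort tibble (typically matched).
#' @return Tibble with `arm`, `time`, `survival`, `n_risk`, `lower`, `upper`.
#' @export
km_by_arm <- function(cohort) {
  cohort <- check_cohort(cohort)
  purrr::map_dfr(c("vats", "chest_tube"), function(a) {
    sub <- cohort[cohort$arm == a, ]
    fit <- km_fit(sub$time_months, sub$recurrence)
    dplyr::mutate(fit$curve, arm = a, .before = 1)
  })
}

#' Kaplan-Meier plot by arm
#'
#' @param cohort Cohort tibble.
#' @return A ggplot step plot of recurrence-free probability.
#' @export
plot_km <- function(cohort) {
  curves <- km_by_arm(cohort)
  base <- tibble::tibble(
    arm = unique(curves$arm), time = 0, survival = 1,
    n_risk = NA_integer_, lower = 1, upper = 1, n_event = 0L
  )
  dat <- dplyr::bind_rows(base, curves)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival, colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "months since intervention", y = "recurrence-free probability",
      colour = NULL, title = "Recurrence-free interval by treatment arm"
    ) +
    ggplot2::theme_minimal()
}

#' Restate a hazard ratio as a percent hazard reduction
#'
#' @param hr Hazard ratio of treatment versus control.
#' @return `100 * (1 - hr)`.
#' @export
#' @examples
#' hazard_reduction_pct(0.166)
hazard_reduction_pct <- function(hr) {
  if (hr < 0) stop_input("hazard ratio must be non-negative")
  100 * (1 - hr)
}

check_surv_input <- function(times, flags) {
  if (length(times) != length(flags) || length(times) == 0) {
    stop_input("times and event flags must be equal-length, non-empty")
  }
  if (any(times <= 0)) stop_input("times must be positive")
  if (!all(flags %in% c(0, 1))) stop_input("event flags must be 0/1")
  invisible(TRUE)
}
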