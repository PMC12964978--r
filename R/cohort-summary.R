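#' Baseline characteristics table
#'
#' Per-arm counts and percentages for every categorical covariate level and
#' median (IQR) for the continuous variables (age, length of stay, time to
#' recurrence/censoring, total cost), in the layout of a standard
#' before/after-matching baseline table. Quantiles use linear interpolation
#' between order statistics (recorded in the `quantile_rule` attribute).
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param pairing Optional [match_greedy()] result; when given, the summary
#'   is restricted to matched patients.
#' @return A tibble with columns `variable`, `level`, `statistic`
#'   (`n_pct` or `median_iqr`) and per-arm value columns (`vats`,
#'   `chest_tube`) plus numeric helpers (`vats_n`, `vats_pct`, ...).
#' @export
summarize_baseline <- function(cohort, pairing = NULL) {
  cohort <- check_cohort(cohort)
  if (!is.null(pairing)) {
    keep <- c(pairing$pairs$treated_id, pairing$pairs$control_id)
    cohort <- dplyr::filter(cohort, .data$patient_id %in% keep)
    if (nrow(cohort) == 0) stop_input("pairing matches no cohort rows")
  }

  lv <- covariate_levels()
  cat_rows <- purrr::map_dfr(names(lv), function(cov) {
    vals <- cohort_level_values(cohort, cov)
    purrr::map_dfr(lv[[cov]], function(level) {
      per_arm <- purrr::map(c(vats = "vats", chest_tube = "chest_tube"), function(a) {
        x <- vals[cohort$arm == a]
        n <- sum(x == level)
        c(n = n, pct = 100 * n / length(x))
      })
      tibble::tibble(
        variable = cov, level = level, statistic = "n_pct",
        vats_n = per_arm$vats[["n"]], vats_pct = per_arm$vats[["pct"]],
        chest_tube_n = per_arm$chest_tube[["n"]],
        chest_tube_pct = per_arm$chest_tube[["pct"]],
        vats = sprintf("%d (%.1f%%)", per_arm$vats[["n"]], per_arm$vats[["pct"]]),
        chest_tube = sprintf(
          "%d (%.1f%%)", per_arm$chest_tube[["n"]], per_arm$chest_tube[["pct"]]
        )
      )
    })
  })

  cont_vars <- c(
    age_years = "age_years", los_days = "los_days",
    time_months = "time_months", total_cost_cny = "total_cost_cny"
  )
  cont_rows <- purrr::map_dfr(names(cont_vars), function(v) {
    per_arm <- purrr::map(c(vats = "vats", chest_tube = "chest_tube"), function(a) {
      iqr_summary(cohort[[v]][cohort$arm == a])
    })
    fmt <- function(s) sprintf("%.1f (%.1f-%.1f)", s$median, s$q25, s$q75)
    tibble::tibble(
      variable = v, level = NA_character_, statistic = "median_iqr",
      vats_median = per_arm$vats$median, vats_q25 = per_arm$vats$q25,
      vats_q75 = per_arm$vats$q75,
      chest_tube_median = per_arm$chest_tube$median,
      chest_tube_q25 = per_arm$chest_tube$q25,
      chest_tube_q75 = per_arm$chest_tube$q75,
      vats = fmt(per_arm$vats), chest_tube = fmt(per_arm$chest_tube)
    )
  })

  out <- dplyr::bind_rows(cat_rows, cont_rows)
  attr(out, "quantile_rule") <- "linear interpolation between order statistics (type 7)"
  attr(out, "n_per_arm") <- c(
    vats = sum(cohort$arm == "vats"),
    chest_tube = sum(cohort$arm == "chest_tube")
  )
  out
}

# Covariate values as character levels matching covariate_levels()
# (0/1 covariates compare as "0"/"1").
cohort_level_values <- function(cohort, cov) {
  as.character(cohort[[cov]])
}
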