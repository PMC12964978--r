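#' Generate a synthetic pneumothorax cohort
#'
#' Draws `n_per_arm` patients per arm from the generating model in a
#' [cohort_config()]: independent categorical covariates per arm (marginals
#' under the confounding dial), a continuous age consistent with the drawn
#' age stratum, exponential recurrence times under a proportional-hazards
#' law censored administratively at 60 months, and log-normal costs and
#' lengths of stay. Chest-tube patients with recurrence accrue the
#' configured recurrence-management cost; chest-tube patients with
#' prolonged air leak may cross over to rescue VATS, which adds a VATS-scale
#' cost to their total (intention to treat: the arm label never changes).
#'
#' @param config A [cohort_config()].
#' @return A tibble, one row per patient, with columns (in this fixed
#'   order): `patient_id`, `arm` (`vats`/`chest_tube`), `age_years`,
#'   `age_ge45` (0/1), `sex` (`male`/`female`), `smoker` (0/1),
#'   `laterality` (`left`/`right`), `collapse_cat` (`c30_50`/`gt50`),
#'   `bleb_diam_cat` (`lt1cm`/`cm1_5`/`gt5cm`), `bleb_count_cat`
#'   (`n1_2`/`n3_5`/`gt5`), `recurrence` (0/1), `time_months` (0, 60],
#'   `censored` (0/1), `total_cost_cny`, `los_days`, `complication` (0/1),
#'   `crossover_to_vats` (0/1).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_arm = 100, seed = 42))
#' dplyr::count(cohort, arm, recurrence)
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  with_seed(config$seed, {
    arms <- purrr::map(c(vats = "vats", chest_tube = "chest_tube"), function(arm) {
      generate_arm(arm, config)
    })
    out <- dplyr::bind_rows(arms)
  })
  out
}

generate_arm <- function(arm, config) {
  n <- config$n_per_arm
  lv <- covariate_levels()
  m <- config$confounding_multiplier

  draw_cat <- function(cov) {
    p <- dialed_marginal(
      config$covariate_marginals[[cov]]$vats,
      config$covariate_marginals[[cov]]$chest_tube,
      m
    )[[arm]]
    sample(lv[[cov]], n, replace = TRUE, prob = p)
  }

  sex <- draw_cat("sex")
  age_ge45 <- as.integer(draw_cat("age_ge45") == "1")
  smoker <- as.integer(draw_cat("smoker") == "1")
  laterality <- draw_cat("laterality")
  collapse_cat <- draw_cat("collapse_cat")
  bleb_diam_cat <- draw_cat("bleb_diam_cat")
  bleb_count_cat <- draw_cat("bleb_count_cat")

  # continuous age filled in within the drawn stratum (dichotomized at 45)
  age_years <- ifelse(age_ge45 == 1, runif(n, 45, 75), runif(n, 18, 45))

  hazard <- config$baseline_hazard_monthly *
    if (arm == "vats") exp(config$true_log_hr) else 1
  t_raw <- rexp(n, rate = hazard)
  recurrence <- as.integer(t_raw < config$horizon_months)
  time_months <- ifelse(recurrence == 1, t_raw, config$horizon_months)
  censored <- 1L - recurrence

  cost <- rlnorm(n, config$cost_meanlog[[arm]], config$cost_sdlog[[arm]])
  los <- rlnorm(n, config$los_meanlog[[arm]], config$los_sdlog[[arm]])
  complication <- rbinom(n, 1, config$p_complication[[arm]])

  crossover <- integer(n)
  if (arm == "chest_tube") {
    # PAL is a subset of complications; crossover adds a VATS-scale cost
    p_pal_given_comp <- min(1, config$p_pal_chest_tube / config$p_complication[["chest_tube"]])
    pal <- complication * rbinom(n, 1, p_pal_given_comp)
    crossover <- pal * rbinom(n, 1, config$crossover_prob_given_pal)
    cost <- cost +
      crossover * rlnorm(n, config$cost_meanlog[["vats"]], config$cost_sdlog[["vats"]]) +
      recurrence * config$recurrence_cost_cny
  }

  tibble::tibble(
    patient_id = sprintf("%s_%05d", if (arm == "vats") "v" else "c", seq_len(n)),
    arm = arm,
    age_years = age_years,
    age_ge45 = age_ge45,
    sex = sex,
    smoker = smoker,
    laterality = laterality,
    collapse_cat = collapse_cat,
    bleb_diam_cat = bleb_diam_cat,
    bleb_count_cat = bleb_count_cat,
    recurrence = recurrence,
    time_months = time_months,
    censored = censored,
    total_cost_cny = cost,
    los_days = los,
    complication = complication,
    crossover_to_vats = crossover
  )
}

cohort_columns <- function() {
  c(
    "patient_id", "arm", "age_years", "age_ge45", "sex", "smoker",
    "laterality", "collapse_cat", "bleb_diam_cat", "bleb_count_cat",
    "recurrence", "time_months", "censored", "total_cost_cny", "los_days",
    "complication", "crossover_to_vats"
  )
}

#' Write and read cohort CSV files
#'
#' Cohorts are exchanged as UTF-8 CSV with a header, "." decimal separator
#' and the fixed column order documented in [generate_cohort()]. `write_cohort_csv()`
#' also writes a sidecar JSON (`<path>.config.json`) recording the
#' generating configuration when one is supplied.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @param config Optional [cohort_config()] stored alongside the CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, config = NULL) {
  check_cohort(cohort)
  readr::write_csv(cohort[, cohort_columns()], path)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @param allow_extra Permit (and drop) unknown columns instead of erroring.
#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, allow_extra = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing) > 0) {
    stop_input("cohort CSV is missing columns: %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), cohort_columns())
  if (length(extra) > 0 && !allow_extra) {
    stop_input(
      "cohort CSV has unknown columns: %s (set allow_extra = TRUE to drop them)",
      paste(extra, collapse = ", ")
    )
  }
  check_cohort(df[, cohort_columns()])
}

# Schema and invariant checks shared by the generator and the CSV reader.
check_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  if (!all(cohort$arm %in% c("vats", "chest_tube"))) {
    stop_input("arm must be 'vats' or 'chest_tube'")
  }
  if (any(cohort$recurrence == 1 & (cohort$censored != 0 | cohort$time_months >= 60))) {
    stop_input("recurrent patients must be uncensored with time_months < 60")
  }
  if (any(cohort$recurrence == 0 & (cohort$censored != 1 | cohort$time_months != 60))) {
    stop_input("non-recurrent patients must be censored at the 60-month horizon")
  }
  if (any(cohort$crossover_to_vats == 1 & cohort$arm != "chest_tube")) {
    stop_input("crossover_to_vats may be 1 only in the chest-tube arm")
  }
  if (any(cohort$total_cost_cny <= 0) || any(cohort$time_months <= 0)) {
    stop_input("costs and event times must be strictly positive")
  }
  tibble::as_tibble(cohort)
}
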