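#' Fit the propensity-score model
#'
#' Logistic regression of treatment (VATS = 1) on the seven baseline
#' covariates: sex, the age-at-45 indicator, smoking status, laterality,
#' degree of lung collapse, maximum bleb diameter and bleb count (the two
#' three-level covariates dummy-coded against their first level). Age
#' enters as the binary >= 45 indicator, mirroring how the balance table
#' stratifies age.
#'
#' @param cohort Cohort tibble with both arms present.
#' @return A `propensity_fit` with elements `coefficients`,
#'   `linear_predictor` (logit of the propensity score, one per patient,
#'   named by `patient_id`), `propensity`, `converged`, `n_iterations`,
#'   `model` (the underlying `glm`), and `data` (the cohort).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_arm = 200, seed = 3))
#' fit <- fit_propensity(cohort)
#' head(tidy(fit))
fit_propensity <- function(cohort) {
  cohort <- check_cohort(cohort)
  if (length(unique(cohort$arm)) < 2) {
    stop_input("both treatment arms must be present to fit a propensity model")
  }
  dat <- dplyr::mutate(cohort,
    treated = as.integer(.data$arm == "vats"),
    sex = factor(.data$sex, covariate_levels()$sex),
    laterality = factor(.data$laterality, covariate_levels()$laterality),
    collapse_cat = factor(.data$collapse_cat, covariate_levels()$collapse_cat),
    bleb_diam_cat = factor(.data$bleb_diam_cat, covariate_levels()$bleb_diam_cat),
    bleb_count_cat = factor(.data$bleb_count_cat, covariate_levels()$bleb_count_cat)
  )
  terms <- c(
    "sex", "age_ge45", "smoker", "laterality", "collapse_cat",
    "bleb_diam_cat", "bleb_count_cat"
  )
  # drop covariates with a single observed level so the design stays full rank
  terms <- terms[vapply(terms, function(t) length(unique(dat[[t]])) > 1, logical(1))]
  if (length(terms) == 0) stop_input("no covariate varies; nothing to model")
  fml <- stats::as.formula(paste("treated ~", paste(terms, collapse = " + ")))
  model <- suppressWarnings(glm(fml, family = binomial(), data = dat,
    control = list(epsilon = 1e-12, maxit = 100)
  ))
  if (any(is.na(coef(model)))) {
    bad <- names(coef(model))[is.na(coef(model))]
    abort(
      sprintf("collinear design: coefficient(s) not estimable: %s",
        paste(bad, collapse = ", ")),
      class = "pneumocea_collinearity_error"
    )
  }
  p <- fitted(model)
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    sep_rows <- which(p < 1e-10 | p > 1 - 1e-10)
    pattern <- dat[sep_rows[1], terms, drop = FALSE]
    abort(
      sprintf(
        "separation: fitted propensity within 1e-10 of 0/1 for %d patient(s); first offending covariate pattern: %s",
        length(sep_rows),
        paste(sprintf("%s=%s", names(pattern), unlist(lapply(pattern, as.character))),
          collapse = ", ")
      ),
      class = "pneumocea_separation_error"
    )
  }
  lp <- stats::predict(model, type = "link")
  names(lp) <- dat$patient_id
  structure(
    list(
      coefficients = coef(model),
      linear_predictor = lp,
      propensity = stats::setNames(p, dat$patient_id),
      converged = model$converged,
      n_iterations = model$iter,
      model = model,
      data = cohort
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity model (logistic, VATS = 1):",
    length(x$coefficients), "coefficients,",
    length(x$linear_predictor), "patients;",
    if (x$converged) "converged" else "NOT converged",
    sprintf("in %d iterations\n", x$n_iterations)
  )
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a propensity fit
#'
#' @param x A `propensity_fit`.
#' @param ... Unused.
#' @return Coefficient-level tibble (term, estimate, std.error, statistic,
#'   p.value).
#' @exportS3Method generics::tidy
tidy.propensity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname tidy.propensity_fit
#' @return For `glance()`: one-row model-level tibble.
#' @exportS3Method generics::glance
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$linear_predictor),
    n_treated = sum(x$model$y),
    null.deviance = x$model$null.deviance,
    deviance = x$model$deviance,
    AIC = stats::AIC(x$model),
    converged = x$converged,
    n_iterations = x$n_iterations
  )
}
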