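#' Standardized mean difference
#'
#' Scale-free imbalance between two groups. Continuous:
#' `|mean_a - mean_b| / sqrt((var_a + var_b) / 2)` with sample variances.
#' Binary (0/1 values): `|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)`.
#' Returns 0 when both numerator and denominator vanish (identical
#' degenerate groups); a zero pooled variance with a non-zero mean
#' difference is an error. Values below 0.1 are conventionally negligible.
#'
#' @param values_a,values_b Numeric vectors, one per group.
#' @param kind `"continuous"` or `"binary"`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' smd(c(1, 2, 3), c(1, 2, 3))
#' smd(rbinom(100, 1, 0.6), rbinom(100, 1, 0.4), kind = "binary")
smd <- function(values_a, values_b, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop_input("both groups must be non-empty")
  }
  if (kind == "binary") {
    if (!all(c(values_a, values_b) %in% c(0, 1))) {
      stop_input("binary SMD requires 0/1 values")
    }
    pa <- mean(values_a)
    pb <- mean(values_b)
    num <- abs(pa - pb)
    den <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
  } else {
    num <- abs(mean(values_a) - mean(values_b))
    den <- sqrt((var(values_a) + var(values_b)) / 2)
  }
  if (den == 0 || is.na(den)) {
    if (num == 0) return(0)
    abort("degenerate variance: zero pooled variance with non-zero mean difference",
      class = "pneumocea_degenerate_variance_error"
    )
  }
  num / den
}

#' Covariate balance before and after matching
#'
#' Per-level binary SMDs for every categorical covariate (three-level
#' covariates expanded to one-vs-rest indicators; two-level covariates
#' contribute their index level once), computed on the full cohort
#' (pre-match) and on matched patients only (post-match). The mean SMD is
#' the unweighted arithmetic mean over the reported levels — continuous age
#' is excluded, its binary >= 45 indicator included — recorded in the
#' `averaging_set` attribute.
#'
#' @param cohort Cohort tibble.
#' @param fit The [fit_propensity()] result used for matching (kept for
#'   provenance; balance itself is covariate-based).
#' @param match A [match_greedy()] result. With an empty match, post-match
#'   SMDs are `NA` (undefined), not zero.
#' @return A `balance_report`: tibble with `covariate`, `level`, `smd_pre`,
#'   `smd_post`, plus attributes `mean_smd_pre`, `mean_smd_post`.
#' @export
balance_report <- function(cohort, fit, match) {
  cohort <- check_cohort(cohort)
  levels_tbl <- balance_levels()
  matched <- if (nrow(match$pairs) > 0) matched_cohort(cohort, match) else NULL

  one <- function(data, cov, level) {
    ind <- as.integer(cohort_level_values(data, cov) == level)
    smd(ind[data$arm == "vats"], ind[data$arm == "chest_tube"], kind = "binary")
  }
  rows <- purrr::pmap_dfr(levels_tbl, function(covariate, level) {
    tibble::tibble(
      covariate = covariate, level = level,
      smd_pre = one(cohort, covariate, level),
      smd_post = if (is.null(matched)) NA_real_ else one(matched, covariate, level)
    )
  })
  out <- structure(rows, class = c("balance_report", class(rows)))
  attr(out, "mean_smd_pre") <- mean(rows$smd_pre)
  attr(out, "mean_smd_post") <- if (is.null(matched)) NA_real_ else mean(rows$smd_post)
  attr(out, "averaging_set") <-
    "unweighted mean over one-vs-rest level SMDs; continuous age excluded, age_ge45 included"
  attr(out, "n_pairs") <- nrow(match$pairs)
  out
}

# Reported one-vs-rest levels: index level for binary covariates, every
# level for multi-category ones.
balance_levels <- function() {
  tibble::tribble(
    ~covariate, ~level,
    "sex", "male",
    "age_ge45", "1",
    "smoker", "1",
    "laterality", "left",
    "collapse_cat", "gt50",
    "bleb_diam_cat", "lt1cm",
    "bleb_diam_cat", "cm1_5",
    "bleb_diam_cat", "gt5cm",
    "bleb_count_cat", "n1_2",
    "bleb_count_cat", "n3_5",
    "bleb_count_cat", "gt5"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf(
    "Balance over %d covariate levels (%d matched pairs): mean SMD %.3f pre, %s post\n",
    nrow(x), attr(x, "n_pairs"), attr(x, "mean_smd_pre"),
    if (is.na(attr(x, "mean_smd_post"))) "undefined" else
      sprintf("%.3f", attr(x, "mean_smd_post"))
  ))
  NextMethod()
}

#' Love plot of covariate balance
#'
#' Dot plot of per-level SMDs before and after matching with the
#' conventional 0.1 reference line.
#'
#' @param object A `balance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.balance_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("smd_pre", "smd_post"),
    names_to = "stage", values_to = "smd"
  )
  long$stage <- factor(long$stage, c("smd_pre", "smd_post"), c("pre-match", "post-match"))
  long$label <- paste(long$covariate, long$level, sep = ": ")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$smd, y = .data$label, colour = .data$stage)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(
      x = "standardized mean difference", y = NULL, colour = NULL,
      title = "Covariate balance before and after matching"
    ) +
    ggplot2::theme_minimal()
}

#' Export a balance report as CSV
#'
#' @param report A `balance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_balance_csv <- function(report, path) {
  out <- tibble::as_tibble(report)
  out$mean_smd_pre <- attr(report, "mean_smd_pre")
  out$mean_smd_post <- attr(report, "mean_smd_post")
  readr::write_csv(out, path)
  invisible(path)
}
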