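#' Recurrence 2x2 table and effect measures
#'
#' `two_by_two()` bundles recurrence counts; `effect_summary()` turns them
#' into the comparative-effectiveness measures: per-arm recurrence rates,
#' absolute risk reduction (ARR = control rate minus treated rate), number
#' needed to treat (NNT = 1/ARR, reported as `Inf` with a note when ARR is
#' not positive), and relative risk. Raw values are kept at full precision;
#' the `*_pct` columns carry the conventional presentation rounding (one
#' decimal for percentages, two for NNT).
#'
#' @param events_treated,n_treated,events_control,n_control Integer counts.
#' @return `two_by_two()`: a `two_by_two` list. `effect_summary()`: a
#'   one-row tibble.
#' @export
#' @examples
#' effect_summary(two_by_two(4, 33, 16, 33))
two_by_two <- function(events_treated, n_treated, events_control, n_control) {
  if (n_treated <= 0 || n_control <= 0) stop_input("arm sizes must be positive")
  if (events_treated > n_treated || events_control > n_control ||
      events_treated < 0 || events_control < 0) {
    stop_input("event counts must lie in [0, n] for each arm")
  }
  structure(
    list(
      events_treated = events_treated, n_treated = n_treated,
      events_control = events_control, n_control = n_control
    ),
    class = "two_by_two"
  )
}

#' @param t A `two_by_two`.
#' @rdname two_by_two
#' @export
effect_summary <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  rate_t <- t$events_treated / t$n_treated
  rate_c <- t$events_control / t$n_control
  arr <- rate_c - rate_t
  nnt <- if (arr > 0) 1 / arr else Inf
  rr <- if (rate_c > 0) rate_t / rate_c else NA_real_
  tibble::tibble(
    rate_treated = rate_t,
    rate_control = rate_c,
    arr = arr,
    nnt = nnt,
    rr = rr,
    nnt_defined = arr > 0,
    arr_sign = sign(arr),
    rate_treated_pct = round(100 * rate_t, 1),
    rate_control_pct = round(100 * rate_c, 1),
    arr_pct = round(100 * arr, 1),
    nnt_2dp = if (is.finite(nnt)) round(nnt, 2) else NA_real_
  )
}

#' McNemar's test for matched pairs
#'
#' Tests marginal homogeneity from the discordant-pair counts `b` (treated
#' event, control none) and `c` (control event, treated none). `"exact"`
#' doubles the smaller binomial tail of `X ~ Binomial(b + c, 1/2)`, capped
#' at 1; `"chi_square"` uses `(|b - c| - cc)^2 / (b + c)` on one degree of
#' freedom with continuity correction `cc = 1` by default.
#'
#' @param discordant_tc,discordant_ct Discordant counts `b` and `c`.
#' @param mode `"exact"` or `"chi_square"`.
#' @param continuity_correction Used by the chi-square mode.
#' @return One-row tibble with `statistic` (chi-square mode only),
#'   `p_value`, `mode`, and a `degenerate` flag (`b + c = 0` gives p = 1).
#' @export
#' @examples
#' mcnemar_test(2, 14)
mcnemar_test <- function(discordant_tc, discordant_ct,
                         mode = c("exact", "chi_square"),
                         continuity_correction = TRUE) {
  mode <- match.arg(mode)
  b <- discordant_tc
  c_ <- discordant_ct
  if (b < 0 || c_ < 0) stop_input("discordant counts must be non-negative")
  n <- b + c_
  if (n == 0) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = 1, mode = mode, degenerate = TRUE
    ))
  }
  if (mode == "exact") {
    p <- min(1, 2 * pbinom(min(b, c_), n, 0.5))
    tibble::tibble(statistic = NA_real_, p_value = p, mode = mode, degenerate = FALSE)
  } else {
    cc <- if (continuity_correction) 1 else 0
    stat <- (max(0, abs(b - c_) - cc))^2 / n
    tibble::tibble(
      statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      mode = mode, degenerate = FALSE
    )
  }
}
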