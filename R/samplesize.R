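#' Two-independent-proportions sample size
#'
#' Normal-approximation per-group requirement for detecting `p1` versus
#' `p2` at two-sided level `alpha` with the given power. The pooled
#' variant uses the pooled proportion in the null-variance term,
#' `n = (z_{a/2} sqrt(2 pbar qbar) + z_b sqrt(p1 q1 + p2 q2))^2 / (p1 - p2)^2`;
#' the unpooled variant uses
#' `n = (z_{a/2} + z_b)^2 (p1 q1 + p2 q2) / (p1 - p2)^2`.
#' The result is rounded up to the next whole patient.
#'
#' @param p1,p2 Anticipated proportions, `0 < p2 < p1 < 1`.
#' @param alpha Two-sided type-I error.
#' @param power Target power (1 - beta).
#' @param variant `"unpooled"` or `"pooled"`.
#' @return Integer per-group count.
#' @export
#' @examples
#' sample_size_two_props(0.456, 0.117)
sample_size_two_props <- function(p1, p2, alpha = 0.05, power = 0.80,
                                  variant = c("unpooled", "pooled")) {
  variant <- match.arg(variant)
  if (!(p2 < p1 && p1 < 1 && p2 > 0)) stop_input("require 0 < p2 < p1 < 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_input("alpha and power must lie in (0, 1)")
  }
  if (p1 == p2) stop_input("p1 = p2: effect size is zero")
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  q1 <- 1 - p1
  q2 <- 1 - p2
  n <- if (variant == "pooled") {
    pbar <- (p1 + p2) / 2
    (za * sqrt(2 * pbar * (1 - pbar)) + zb * sqrt(p1 * q1 + p2 * q2))^2 / (p1 - p2)^2
  } else {
    (za + zb)^2 * (p1 * q1 + p2 * q2) / (p1 - p2)^2
  }
  as.integer(ceiling(n))
}

#' Inflate a per-group sample size for anticipated attrition
#'
#' @param n Per-group count.
#' @param factor Inflation factor (e.g. 1.2 for 20% attrition allowance).
#' @return `ceiling(n * factor)` as an integer.
#' @export
#' @examples
#' inflate_sample_size(26, 1.2)
inflate_sample_size <- function(n, factor) {
  if (factor < 1) stop_input("inflation factor must be >= 1")
  as.integer(ceiling(n * factor))
}

#' Power of the two-proportion normal-approximation test
#'
#' Inverse of [sample_size_two_props()] (unpooled variant): achieved power
#' at per-group size `n`.
#'
#' @inheritParams sample_size_two_props
#' @param n Per-group count.
#' @return Power in (0, 1).
#' @export
power_two_props <- function(p1, p2, n, alpha = 0.05) {
  za <- qnorm(1 - alpha / 2)
  se <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / n)
  pnorm(abs(p1 - p2) / se - za)
}
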