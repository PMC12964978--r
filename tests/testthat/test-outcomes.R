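test_that("effect measures satisfy their identities on the matched counts", {
  eff <- effect_summary(two_by_two(4, 33, 16, 33))
  expect_equal(eff$rate_treated_pct, 12.1)
  expect_equal(eff$rate_control_pct, 48.5)
  expect_equal(eff$arr_pct, 36.4)
  expect_equal(eff$nnt, 33 / 12) # exact rational identity
  expect_equal(eff$nnt * eff$arr, 1)
  expect_equal(eff$nnt_2dp, 2.75)

  null <- effect_summary(two_by_two(5, 10, 5, 10))
  expect_equal(null$arr, 0)
  expect_false(null$nnt_defined)
  expect_equal(null$nnt, Inf)

  extreme <- effect_summary(two_by_two(0, 10, 10, 10))
  expect_equal(extreme$arr, 1)
  expect_equal(extreme$nnt, 1)
  expect_equal(extreme$rr, 0)
})

test_that("exact McNemar equals the binomial-tail summation", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  # direct oracle: 2 * sum_{k<=min(b,c)} C(b+c, k) / 2^(b+c)
  expect_equal(
    mcnemar_test(14, 2)$p_value,
    2 * sum(choose(16, 0:2)) / 2^16
  )
  expect_equal(mcnemar_test(12, 0)$p_value, 2 / 4096)
  expect_true(mcnemar_test(0, 0)$degenerate)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
})

test_that("exact and chi-square McNemar converge as discordant pairs grow", {
  gap <- vapply(c(10, 100, 1000), function(n) {
    b <- round(0.6 * n)
    abs(mcnemar_test(b, n - b)$p_value -
      mcnemar_test(b, n - b, mode = "chi_square")$p_value)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
})

test_that("KM reproduces hand product-limit results and the empirical survivor", {
  fit <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(fit$curve$survival, c(0.75, 0.5, 0.25, 0))

  fit2 <- km_fit(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(fit2$curve$survival[fit2$curve$time == 1], 0.75)
  expect_equal(fit2$curve$survival[fit2$curve$time == 3], 0.375) # (3/4)(1/2)

  # no censoring: KM equals the empirical survivor function (property)
  for (s in 1:10) {
    set.seed(s)
    t <- sample(1:20, 12, replace = TRUE)
    fit3 <- km_fit(t, rep(1, 12))
    emp <- vapply(fit3$curve$time, function(x) mean(t > x), numeric(1))
    expect_equal(fit3$curve$survival, emp)
  }
})

test_that("KM median is not reached when the curve stays above one half", {
  times <- c(rep(60, 29), 10, 20, 30, 40)
  flags <- c(rep(0, 29), 1, 1, 1, 1) # 4 events of 33: VATS-like arm
  fit <- km_fit(times, flags)
  expect_false(fit$median_reached)
  expect_true(all(fit$curve$survival > 0.5))

  none <- km_fit(c(60, 60, 50), c(0, 0, 0))
  expect_true(all(none$curve$survival == 1))
  expect_false(none$median_reached)
})

test_that("log-rank matches a term-by-term oracle and is null-calibrated", {
  expect_equal(logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))$statistic, 0)
  expect_equal(logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))$p_value, 1)

  ta <- c(2, 5, 8)
  fa <- c(1, 1, 0)
  tb <- c(1, 4, 9)
  fb <- c(1, 0, 1)
  expect_equal(
    logrank_test(ta, fa, tb, fb)$statistic,
    logrank_by_hand(ta, fa, tb, fb),
    tolerance = 1e-10
  )

  expect_error(
    logrank_test(c(1, 1), c(0, 0), c(1, 1), c(0, 0)),
    class = "pneumocea_input_error"
  )
})

test_that("Cox log HR matches brute-force partial-likelihood maximization", {
  set.seed(4)
  for (rep in 1:5) {
    t <- round(stats::rexp(6, 0.2) + 0.1, 3) # no ties
    x <- c(1, 1, 1, 0, 0, 0)
    fl <- rbinom(6, 1, 0.8)
    if (sum(fl[x == 1]) == 0 || sum(fl[x == 0]) == 0) next
    fit <- cox_fit(t, fl, x)
    oracle <- stats::optimize(
      function(b) breslow_loglik(b, t, fl, x),
      c(-10, 10),
      maximum = TRUE, tol = 1e-10
    )$maximum
    expect_equal(fit$log_hr, oracle, tolerance = 1e-4)
    expect_equal(fit$hr, exp(fit$log_hr))
    expect_equal(fit$ci95, exp(fit$log_hr + c(-1, 1) * qnorm(0.975) * fit$se))
  }
})

test_that("Cox and log-rank score agree with one binary covariate, no ties", {
  set.seed(12)
  t <- round(stats::rexp(30, 0.1), 6)
  x <- rep(c(1, 0), 15)
  fl <- rbinom(30, 1, 0.7)
  lr <- logrank_test(t[x == 1], fl[x == 1], t[x == 0], fl[x == 0])
  sc <- summary(cox_fit(t, fl, x)$coxph)$sctest[["test"]]
  expect_equal(lr$statistic, sc, tolerance = 1e-3)
})

test_that("Cox recovers a null effect and flags monotone likelihoods", {
  ch <- generate_cohort(study_config(1500, seed = 19, true_log_hr = 0))
  fit <- cox_fit(ch$time_months, ch$recurrence, ch$arm == "vats")
  expect_lt(abs(fit$log_hr) / fit$se, 3)

  # every event in one group long before any other-group event diverges
  t <- c(1, 2, 3, 50, 55, 58)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_error(
    cox_fit(t, rep(1, 6), x),
    class = "pneumocea_divergence_error"
  )
})

test_that("rank tests cover paired, unpaired and degenerate cases", {
  expect_true(rank_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$degenerate)
  expect_equal(rank_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE)$p_value, 1)

  u <- rank_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$statistic, 0) # complete rank separation

  # exhaustive sign-flip oracle for the paired signed-rank p-value
  a <- c(3.1, 4.2, 1.0, 5.5, 2.2)
  b <- c(2.0, 1.1, 3.0, 1.5, 2.0)
  d <- a - b
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  w_all <- as.matrix(signs) %*% r
  p_exact <- mean(abs(w_all - sum(r) / 2) >= abs(w_obs - sum(r) / 2))
  p_pkg <- rank_tests(a, b, paired = TRUE)$p_value
  expect_lt(abs(p_pkg - p_exact), 0.12) # normal approximation at n = 5
})

test_that("two-proportion sample size matches the formulas and its power claim", {
  expect_equal(sample_size_two_props(0.456, 0.117), 24L)
  za <- qnorm(0.975)
  zb <- qnorm(0.8)
  pbar <- (0.456 + 0.117) / 2
  n_pooled <- ceiling(
    (za * sqrt(2 * pbar * (1 - pbar)) +
      zb * sqrt(0.456 * 0.544 + 0.117 * 0.883))^2 / (0.456 - 0.117)^2
  )
  expect_equal(sample_size_two_props(0.456, 0.117, variant = "pooled"), as.integer(n_pooled))

  expect_equal(inflate_sample_size(26, 1.2), 32L)

  # numeric power inversion: the returned n achieves the requested power
  for (p in list(c(0.456, 0.117), c(0.4, 0.2), c(0.3, 0.1))) {
    n <- sample_size_two_props(p[1], p[2], power = 0.8)
    expect_gte(power_two_props(p[1], p[2], n), 0.8)
    expect_lt(power_two_props(p[1], p[2], n - 2), 0.8)
  }

  expect_error(sample_size_two_props(0.3, 0.3), class = "pneumocea_input_error")
})
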