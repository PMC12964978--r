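test_that("QALY trajectory reproduces closed-form values", {
  # utility 1 everywhere, no discounting: exactly 5 years
  u1 <- utility_set(u_stable = 1, u_pneumothorax = 1, u_post_recovery = 1)
  expect_equal(
    as.numeric(qaly_trajectory(FALSE, NULL, u1, episode_spec(), discount_spec(0))),
    5
  )
  # default initial episode: 0.7 for 14 days then 1.0
  expect_equal(
    as.numeric(qaly_trajectory(FALSE, NULL, utility_set(), episode_spec(), discount_spec(0))),
    5 - 0.3 * (14 / 365)
  )
  # constant utility, positive rate: (1 - exp(-5 rho)) / rho, decreasing in r
  q <- vapply(c(0.03, 0.06, 0.1), function(r) {
    as.numeric(qaly_trajectory(FALSE, NULL, u1, episode_spec(), discount_spec(r)))
  }, numeric(1))
  rho <- log(1 + c(0.03, 0.06, 0.1))
  expect_equal(q, (1 - exp(-5 * rho)) / rho)
  expect_true(all(diff(q) < 0))
})

test_that("discounting is monotone and episodes truncate at the horizon", {
  for (rec in c(FALSE, TRUE)) {
    q <- vapply(c(0, 0.03, 0.06), function(r) {
      as.numeric(qaly_trajectory(
        rec, if (rec) 30 else NULL, utility_set(), episode_spec(), discount_spec(r)
      ))
    }, numeric(1))
    expect_true(all(diff(q) < 0))
  }
  late <- qaly_trajectory(TRUE, 59.9, utility_set(), episode_spec(), discount_spec(0))
  expect_true(attr(late, "truncated"))
  expect_error(
    qaly_trajectory(TRUE, 61, utility_set(), episode_spec(), discount_spec(0)),
    class = "pneumocea_input_error"
  )
})

test_that("QALY accrual agrees with piecewise quadrature on random draws", {
  set.seed(21)
  for (i in 1:12) {
    u <- utility_set(
      u_stable = runif(1, 0.8, 1), u_pneumothorax = runif(1, 0.3, 0.8),
      u_post_recovery = runif(1, 0.7, 1)
    )
    ep <- episode_spec(
      d_initial_days = runif(1, 5, 30), d_recurrence_days = runif(1, 5, 30)
    )
    rate <- sample(c(0, 0.03, 0.06), 1)
    rec <- i %% 2 == 0
    t_rec <- runif(1, 1, 59)
    got <- as.numeric(qaly_trajectory(
      rec, if (rec) t_rec else NULL, u, ep, discount_spec(rate)
    ))
    want <- qaly_by_quadrature(rec, t_rec, u, ep, rate)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("annual-cycle accrual matches a direct yearly sum", {
  u1 <- utility_set(u_stable = 1, u_pneumothorax = 1, u_post_recovery = 1)
  got <- as.numeric(qaly_trajectory(
    FALSE, NULL, u1, episode_spec(), discount_spec(0.03), accrual = "annual_cycle"
  ))
  expect_equal(got, sum(1.03^-(0:4)))
})

test_that("cohort effects are linear in the recurrence count", {
  arm <- rep(c("vats", "chest_tube"), each = 33)
  rec <- c(rep(1, 4), rep(0, 29), rep(1, 16), rep(0, 17))
  ch <- toy_cohort(arm, recurrence = rec, time_months = ifelse(rec == 1, 15, 60))
  ch$pair_id <- rep(1:33, 2)
  eff <- cohort_effects(ch)
  dq <- eff$qalys[eff$arm == "vats"] - eff$qalys[eff$arm == "chest_tube"]
  per_loss <- as.numeric(qaly_trajectory(FALSE, NULL, utility_set(), episode_spec(), discount_spec(0))) -
    as.numeric(qaly_trajectory(TRUE, 15, utility_set(), episode_spec(), discount_spec(0)))
  expect_equal(dq, 12 * per_loss)
  expect_equal(eff$recurrences, c(16, 4))
  expect_true(all(eff$qalys <= 33 * 5))

  two <- toy_cohort(c("vats", "chest_tube"))
  expect_equal(cohort_effects(two)$qalys[1], cohort_effects(two)$qalys[2])
  expect_error(
    cohort_effects(toy_cohort(c("vats", "vats", "chest_tube"))),
    class = "pneumocea_input_error"
  )
})

test_that("CEA reproduces the printed desk-scale arithmetic", {
  t22 <- two_by_two(4, 33, 16, 33)
  cea <- compute_cea(17813, 33, t22, 3.67, arr_digits = 3)
  expect_equal(round(cea$icer_per_recurrence), 48937)
  expect_equal(cea$delta_cost_cohort, 587829)
  expect_equal(cea$icer_per_qaly * cea$delta_qaly_cohort, cea$delta_cost_cohort,
    tolerance = 1e-12
  )
  expect_equal(unname(attr(cea, "wtp_thresholds")), c(95749, 3 * 95749))

  full <- compute_cea(17813, 33, t22, 3.67)
  expect_equal(full$icer_per_recurrence, 17813 / (12 / 33))
})

test_that("ICERs are bilinear in cost and scale-free in cohort size", {
  t22 <- two_by_two(4, 33, 16, 33)
  base <- compute_cea(17813, 33, t22, 3.67)
  twice_cost <- compute_cea(2 * 17813, 33, t22, 3.67)
  expect_equal(twice_cost$icer_per_qaly, 2 * base$icer_per_qaly)
  expect_equal(twice_cost$icer_per_recurrence, 2 * base$icer_per_recurrence)

  bigger <- compute_cea(17813, 66, two_by_two(8, 66, 32, 66), 2 * 3.67)
  expect_equal(bigger$icer_per_recurrence, base$icer_per_recurrence)
  expect_equal(bigger$icer_per_qaly, base$icer_per_qaly)

  zero <- compute_cea(0, 33, t22, 1)
  expect_equal(zero$icer_per_qaly, 0)
  expect_true(zero$cost_effective_1x && zero$cost_effective_3x)

  undef <- compute_cea(100, 33, t22, 0)
  expect_true(is.na(undef$icer_per_qaly))

  dominant <- compute_cea(-100, 33, t22, 1)
  expect_true(dominant$dominant)
})
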