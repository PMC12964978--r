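test_that("propensity coefficient matches the closed-form log odds ratio", {
  # exposure level 1: 30 treated / 20 control; level 0: 10 treated / 40 control
  arm <- c(rep("vats", 40), rep("chest_tube", 60))
  smoker <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  fit <- fit_propensity(toy_cohort(arm, smoker = smoker))
  expect_equal(unname(fit$coefficients["smoker"]), log(6), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$propensity > 0 & fit$propensity < 1))
})

test_that("a non-confounding covariate gets a near-zero coefficient", {
  ch <- generate_cohort(study_config(5000, seed = 13, confounding_multiplier = 0))
  td <- generics::tidy(fit_propensity(ch))
  smo <- td[td$term == "smoker", ]
  expect_lt(abs(smo$estimate / smo$std.error), 3)
})

test_that("perfect separation is detected and named", {
  arm <- c(rep("vats", 20), rep("chest_tube", 20))
  smoker <- c(rep(1, 20), rep(0, 20))
  expect_error(
    fit_propensity(toy_cohort(arm, smoker = smoker)),
    "smoker", class = "pneumocea_separation_error"
  )
})

test_that("greedy matching handles exact and caliper-excluded cases", {
  m <- match_greedy(fake_fit(c(0, 1), c(0, 1)),
    caliper = 0.1, caliper_mode = "absolute"
  )
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$logit_distance, c(0, 0))

  m2 <- match_greedy(fake_fit(0, c(0.5, 0.6)),
    caliper = 0.4, caliper_mode = "absolute"
  )
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$n_unmatched_treated, 1)

  m3 <- match_greedy(fake_fit(0, numeric(0)),
    caliper = 0.4, caliper_mode = "absolute"
  )
  expect_equal(nrow(m3$pairs), 0)

  expect_error(
    match_greedy(fake_fit(0, 0), caliper = -1),
    class = "pneumocea_config_error"
  )
})

test_that("greedy total distance is bounded below by the exhaustive optimum", {
  for (s in 1:20) {
    set.seed(s)
    n_t <- sample(2:4, 1)
    n_c <- sample(2:4, 1)
    t_lp <- round(stats::rnorm(n_t), 2)
    c_lp <- round(stats::rnorm(n_c), 2)
    cal <- stats::runif(1, 0.3, 2)
    m <- match_greedy(fake_fit(t_lp, c_lp), caliper = cal, caliper_mode = "absolute")
    expect_true(all(m$pairs$logit_distance <= cal))
    k <- nrow(m$pairs)
    if (k > 0) {
      opt <- optimal_assignment(t_lp, c_lp, cal, k)
      expect_gte(sum(m$pairs$logit_distance), opt - 1e-12)
    }
  }
})

test_that("matching is one-to-one and deterministic", {
  ch <- generate_cohort(study_config(300, seed = 17))
  fit <- fit_propensity(ch)
  m1 <- match_greedy(fit)
  m2 <- match_greedy(fit)
  expect_identical(m1, m2)
  expect_equal(anyDuplicated(m1$pairs$treated_id), 0)
  expect_equal(anyDuplicated(m1$pairs$control_id), 0)
  expect_lte(nrow(m1$pairs), 300)
  expect_true(all(m1$pairs$logit_distance <= m1$caliper_value))
})

test_that("smd follows the continuous and binary formulas", {
  expect_equal(smd(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0, 1, 2)
  b <- c(-1, 0, 1) # means 1 and 0, both variances 1
  expect_equal(smd(a, b), 1)
  pa <- rep(c(1, 0), c(6, 4))
  pb <- rep(c(1, 0), c(4, 6))
  expect_equal(smd(pa, pb, kind = "binary"), 0.2 / sqrt(0.24))
  expect_equal(smd(c(2, 2), c(2, 2)), 0)
  expect_error(smd(c(1, 1), c(2, 2)), class = "pneumocea_degenerate_variance_error")
})

test_that("balance report agrees with direct smd and zeroes out on exact pairs", {
  arm <- c(rep("vats", 6), rep("chest_tube", 6))
  smoker <- c(1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  ch <- toy_cohort(arm, smoker = smoker)
  fit <- fit_propensity(ch)
  # pair each treated with a covariate-identical control, by construction
  m <- empty_match()
  m$pairs <- tibble::tibble(
    treated_id = ch$patient_id[arm == "vats"],
    control_id = ch$patient_id[arm == "chest_tube"], # same smoker pattern
    logit_distance = 0
  )
  br <- balance_report(ch, fit, m)
  direct <- smd(smoker[arm == "vats"], smoker[arm == "chest_tube"], kind = "binary")
  expect_equal(br$smd_pre[br$covariate == "smoker"], direct)
  expect_true(all(br$smd_post == 0))

  br_empty <- balance_report(ch, fit, empty_match())
  expect_true(all(is.na(br_empty$smd_post)))
  expect_true(is.na(attr(br_empty, "mean_smd_post")))
})

test_that("matching reduces imbalance on a confounded cohort", {
  ch <- generate_cohort(study_config(500, seed = 23))
  fit <- fit_propensity(ch)
  br <- balance_report(ch, fit, match_greedy(fit))
  expect_lt(attr(br, "mean_smd_post"), attr(br, "mean_smd_pre"))
  expect_lt(attr(br, "mean_smd_post"), 0.1)
})
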