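base_case <- function() {
  psa_base_inputs(17813, 33, two_by_two(4, 33, 16, 33), t_recurrence_months = 15)
}

# distributions pinned at the base-case values (se = 0 everywhere)
degenerate_dists <- function(base) {
  list(
    delta_cost_per_patient = list(dist = "gamma", mean = base$delta_cost_per_patient, se = 0),
    u_pneumothorax = list(dist = "beta", mean = 0.7, se = 0),
    u_post_recovery = list(dist = "beta", mean = 0.95, se = 0),
    p_rec_treated = list(dist = "beta", mean = 4 / 33, se = 0),
    p_rec_control = list(dist = "beta", mean = 16 / 33, se = 0)
  )
}

test_that("parameter draws match their moment specifications", {
  cfg <- psa_config(
    n_iterations = 1e5, seed = 3,
    distributions = list(
      u = list(dist = "beta", mean = 0.7, se = 0.07),
      cost = list(dist = "gamma", mean = 17813, se = 3000),
      fixed = list(dist = "beta", mean = 0.4, se = 0)
    )
  )
  u <- draw_parameters(cfg, "u")
  expect_equal(mean(u), 0.7, tolerance = 0.002 / 0.7)
  expect_equal(stats::sd(u), 0.07, tolerance = 0.02)
  expect_true(all(u > 0 & u < 1))
  cost <- draw_parameters(cfg, "cost")
  expect_equal(mean(cost), 17813, tolerance = 0.005)
  expect_true(all(draw_parameters(cfg, "fixed") == 0.4))
})

test_that("infeasible beta moments are rejected by name", {
  expect_error(
    psa_config(distributions = list(bad = list(dist = "beta", mean = 0.5, se = 0.6))),
    "bad", class = "pneumocea_config_error"
  )
})

test_that("draws are deterministic and per-parameter substreams independent", {
  cfg <- psa_config(n_iterations = 100, seed = 42)
  base <- base_case()
  r1 <- run_psa(base, cfg)
  r2 <- run_psa(base, cfg)
  expect_identical(r1$draws, r2$draws)

  dists <- list(
    a = list(dist = "beta", mean = 0.7, se = 0.05),
    b = list(dist = "gamma", mean = 100, se = 10)
  )
  c1 <- psa_config(n_iterations = 50, seed = 5, distributions = dists)
  c2 <- psa_config(
    n_iterations = 50, seed = 5,
    distributions = c(dists, list(zz = list(dist = "beta", mean = 0.5, se = 0.1)))
  )
  expect_identical(draw_parameters(c1, "a"), draw_parameters(c2, "a"))
  expect_identical(draw_parameters(c1, "b"), draw_parameters(c2, "b"))
})

test_that("degenerate distributions collapse the PSA onto the base case", {
  base <- base_case()
  cfg <- psa_config(
    n_iterations = 200, seed = 1,
    distributions = degenerate_dists(base)
  )
  res <- run_psa(base, cfg)
  expect_equal(length(unique(res$draws$delta_cost)), 1)
  expect_equal(length(unique(res$draws$delta_qaly)), 1)
  expect_identical(res$draws$delta_cost[1], res$base_cea$delta_cost_cohort)
  expect_identical(res$draws$delta_qaly[1], res$base_cea$delta_qaly_cohort)
  expect_equal(unname(res$quadrant_counts[["NE"]]), 200)
  # CEAC is a unit step at the base-case ICER
  icer <- res$base_cea$icer_per_qaly
  curve <- ceac(res, c(icer * 0.99, icer * 1.01))
  expect_equal(curve$probability, c(0, 1))
})

test_that("quadrant counts conserve iterations and CEAC is monotone", {
  res <- run_psa(base_case(), psa_config(n_iterations = 2000, seed = 9))
  expect_equal(sum(res$quadrant_counts) + res$n_faulted, 2000)
  expect_true(all(res$draws$delta_qaly > 0) || any(res$quadrant_counts[c("NW", "SW")] > 0))
  if (all(res$draws$delta_qaly > 0)) {
    expect_true(all(diff(res$ceac$probability) >= 0))
  }
  # consistency of the named-threshold probabilities with the curve
  expect_equal(
    unname(res$prob_ce_at[["gdp3"]]),
    ceac(res, 3 * 95749)$probability
  )
  # lambda = 0 reduces the NMB rule to P(delta cost < 0)
  expect_equal(ceac(res, 0)$probability, mean(res$draws$delta_cost < 0))
  # CEAC near the median draw ICER is near one half
  med_icer <- median(res$draws$delta_cost / res$draws$delta_qaly)
  expect_equal(ceac(res, med_icer)$probability, 0.5, tolerance = 2 / sqrt(2000) / 0.5)
})

test_that("scenario engine reproduces the base case and exact linear scalings", {
  base <- base_case()
  tab <- one_way_scenarios(base, list(
    base = list(),
    up = list(cost_multiplier = 1.2),
    down = list(cost_multiplier = 0.8)
  ))
  b <- scenario_cea_row <- tab[tab$scenario == "base", ]
  expect_equal(b$delta_cost, 17813 * 33)
  expect_equal(tab$delta_cost[tab$scenario == "up"], 1.2 * b$delta_cost)
  expect_equal(tab$icer_per_qaly[tab$scenario == "up"], 1.2 * b$icer_per_qaly)
  expect_equal(tab$delta_qaly[tab$scenario == "up"], b$delta_qaly)

  rates <- one_way_scenarios(base, list(
    r0 = list(annual_rate = 0), r3 = list(annual_rate = 0.03),
    r6 = list(annual_rate = 0.06)
  ))
  expect_true(all(diff(rates$delta_qaly) < 0))

  expect_error(
    one_way_scenarios(base, list(x = list(nonsense = 1))),
    "nonsense", class = "pneumocea_config_error"
  )
})

test_that("scenario CE probabilities come from a PSA with the override fixed", {
  base <- base_case()
  tab <- one_way_scenarios(
    base, list(base = list(), cheap = list(cost_multiplier = 0.5)),
    psa = psa_config(n_iterations = 400, seed = 2)
  )
  expect_true(all(tab$ce_probability >= 0 & tab$ce_probability <= 1))
  expect_gte(
    tab$ce_probability[tab$scenario == "cheap"],
    tab$ce_probability[tab$scenario == "base"]
  )
})
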