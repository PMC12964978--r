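# Hand-built cohort rows with full schema; covariates default to constants
# so single-covariate scenarios stay full rank after constant dropping.
toy_cohort <- function(arm, smoker = 0, sex = "male", age_ge45 = 0,
                       laterality = "left", collapse_cat = "c30_50",
                       bleb_diam_cat = "lt1cm", bleb_count_cat = "n1_2",
                       recurrence = 0, time_months = NULL,
                       total_cost_cny = 1000, los_days = 5) {
  n <- length(arm)
  rec <- rep_len(recurrence, n)
  tm <- if (is.null(time_months)) ifelse(rec == 1, 12, 60) else rep_len(time_months, n)
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n)),
    arm = arm,
    age_years = ifelse(rep_len(age_ge45, n) == 1, 50, 30),
    age_ge45 = rep_len(age_ge45, n),
    sex = rep_len(sex, n),
    smoker = rep_len(smoker, n),
    laterality = rep_len(laterality, n),
    collapse_cat = rep_len(collapse_cat, n),
    bleb_diam_cat = rep_len(bleb_diam_cat, n),
    bleb_count_cat = rep_len(bleb_count_cat, n),
    recurrence = rec,
    time_months = tm,
    censored = 1L - rec,
    total_cost_cny = rep_len(total_cost_cny, n),
    los_days = rep_len(los_days, n),
    complication = 0L,
    crossover_to_vats = 0L
  )
}

# Minimal propensity_fit stand-in with prescribed logits, for exercising the
# matcher in isolation.
fake_fit <- function(treated_lp, control_lp) {
  n_t <- length(treated_lp)
  n_c <- length(control_lp)
  ids <- c(sprintf("t%02d", seq_len(n_t)), sprintf("c%02d", seq_len(n_c)))
  lp <- stats::setNames(c(treated_lp, control_lp), ids)
  structure(
    list(
      linear_predictor = lp,
      converged = TRUE,
      data = tibble::tibble(
        patient_id = ids,
        arm = c(rep("vats", n_t), rep("chest_tube", n_c))
      )
    ),
    class = "propensity_fit"
  )
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Pairless match_result, for balance reports of unmatched cohorts.
empty_match <- function() {
  structure(
    list(
      pairs = tibble::tibble(
        treated_id = character(), control_id = character(),
        logit_distance = numeric()
      ),
      caliper_value = 1, caliper_mode = "absolute",
      n_unmatched_treated = 0L, n_unmatched_control = 0L
    ),
    class = "match_result"
  )
}

# Exhaustive minimum-total-distance assignment of k pairs under a caliper
# (oracle for the greedy matcher; k = number of pairs to place).
optimal_assignment <- function(treated_lp, control_lp, caliper, k) {
  n_t <- length(treated_lp)
  n_c <- length(control_lp)
  best <- Inf
  t_sets <- utils::combn(n_t, k, simplify = FALSE)
  c_sets <- utils::combn(n_c, k, simplify = FALSE)
  perms <- perm_all(k)
  for (ts in t_sets) {
    for (cs in c_sets) {
      for (p in perms) {
        d <- abs(treated_lp[ts] - control_lp[cs[p]])
        if (all(d <= caliper)) best <- min(best, sum(d))
      }
    }
  }
  best
}

perm_all <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in perm_all(k - 1L)) out[[length(out) + 1L]] <- c(i, p + (p >= i))
  }
  out
}

# Breslow partial log-likelihood for a single binary covariate, summed
# explicitly (oracle for cox_fit).
breslow_loglik <- function(beta, times, flags, x) {
  ll <- 0
  for (i in which(flags == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Term-by-term two-group log-rank statistic (oracle for logrank_test).
logrank_by_hand <- function(times_a, flags_a, times_b, flags_b) {
  times <- c(times_a, times_b)
  flags <- c(flags_a, flags_b)
  grp <- c(rep(1, length(times_a)), rep(0, length(times_b)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[flags == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(flags == 1 & times == t)
    d1 <- sum(flags == 1 & times == t & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Piecewise trapezoid quadrature of the discounted utility path, with the
# state path reconstructed independently of qaly_trajectory.
qaly_by_quadrature <- function(recurrence, t_rec_months, u, ep, rate,
                               horizon_months = 60, steps = 1e5) {
  horizon <- horizon_months / 12
  d_init <- ep$d_initial_days / 365
  d_rec <- ep$d_recurrence_days / 365
  rho <- log(1 + rate)
  if (recurrence) {
    t_rec <- t_rec_months / 12
    brk <- sort(unique(pmin(
      c(0, min(d_init, t_rec), t_rec, min(t_rec + d_rec, horizon), horizon),
      horizon
    )))
    u_of <- function(t) {
      ifelse(t < min(d_init, t_rec), u$u_pneumothorax,
        ifelse(t < t_rec, u$u_stable,
          ifelse(t < min(t_rec + d_rec, horizon), u$u_pneumothorax,
            u$u_post_recovery)))
    }
  } else {
    brk <- sort(unique(c(0, min(d_init, horizon), horizon)))
    u_of <- function(t) ifelse(t < min(d_init, horizon), u$u_pneumothorax, u$u_stable)
  }
  total <- 0
  for (s in seq_len(length(brk) - 1)) {
    a <- brk[s]
    b <- brk[s + 1]
    if (b <= a) next
    grid <- seq(a, b, length.out = steps)
    u_const <- u_of((a + b) / 2) # utility is constant within a segment
    f <- exp(-rho * grid)
    total <- total + u_const * sum((f[-1] + f[-length(f)]) / 2) * (grid[2] - grid[1])
  }
  total
}

# Default Table-1-calibrated config at a given size/seed.
study_config <- function(n_per_arm, seed, ...) {
  cohort_config(n_per_arm = n_per_arm, seed = seed, ...)
}
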