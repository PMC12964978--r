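# pneumocea

Matched-cohort comparative-effectiveness and cost-effectiveness analysis
for first-episode primary spontaneous pneumothorax (PSP) treatment
strategies: video-assisted thoracoscopic surgery (VATS) versus chest
tube drainage.

## The problem

Roughly half of first-episode PSP patients with CT-confirmed blebs
recur within five years under chest tube drainage; VATS (bullectomy
with pleurodesis) prevents most recurrences at a higher upfront cost.
Whether early surgery is worth it is a joint question of treatment
effect and economics, usually answered from retrospective cohorts that
are confounded by indication. `pneumocea` implements the full analysis
chain for such cohorts, aimed at thoracic-surgery outcomes researchers
and health economists:

- **Propensity-score caliper matching** — logistic propensity model on
  the seven standard baseline covariates (sex, age ≥ 45, smoking,
  laterality, lung-collapse degree, bleb diameter, bleb count), 1:1
  greedy nearest-neighbor matching on the logit within a caliper
  (default 0.02 SD of the logit), standardized-mean-difference (SMD)
  balance diagnostics with the conventional 0.1 threshold and a love
  plot.
- **Effect measures and time-to-event analysis** — recurrence rates,
  ARR, NNT = 1/ARR, relative risk; exact McNemar for matched pairs;
  Kaplan–Meier, log-rank and Cox HR with 95% CI (via the `survival`
  package); Mann–Whitney / Wilcoxon cost comparisons; two-proportion
  sample-size and power calculations.
- **Cost-effectiveness** — a piecewise-constant utility QALY model
  (stable 1.0, pneumothorax episode 0.7, post-recovery 0.95, 14-day
  episodes) with continuous discounting `∫ u(t) e^(−ρt) dt`,
  ρ = log(1 + annual rate); ICER = ΔCost/ΔEffect per QALY gained and
  per recurrence avoided; verdicts against 1× and 3× GDP-per-capita
  willingness-to-pay thresholds (¥95,749 / ¥287,247 per QALY).
- **Sensitivity analysis** — deterministic one-way scenarios (utility,
  episode duration, cost ± 20%, discount 0/3/6%) and probabilistic
  sensitivity analysis (Monte Carlo, default 10,000 iterations; beta
  utilities/probabilities, gamma costs) with cost-effectiveness plane
  quadrants and the acceptability curve from the net-monetary-benefit
  rule λ·ΔQALY − ΔCost > 0.
- **A calibrated synthetic cohort generator** — covariate marginals,
  confounded assignment, an exponential recurrence law (drainage-arm
  five-year recurrence 45.6%, treatment hazard ratio 0.166, 60-month
  administrative censoring) and log-normal costs matching published
  medians/IQRs, so the whole pipeline is testable without patient-level
  data. The generator's confounding strength is a dial
  (`confounding_multiplier`), which the test suite uses to verify that
  matching actually removes the imbalance it is supposed to remove.

Everything is tibble-in/tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods and ggplot2 `autoplot()`/`plot_*()`
helpers; `run_pipeline()` drives all stages from one config and writes
a deterministic CSV + JSON artifact bundle.

## Worked example

```r
library(pneumocea)

cohort <- generate_cohort(cohort_config(n_per_arm = 500, seed = 101))
fit    <- fit_propensity(cohort)
m      <- match_greedy(fit)
m
#> Greedy caliper match: 122 pairs (caliper 0.05727 on logit scale, sd_scaled);
#> 378 treated and 378 controls unmatched

balance_report(cohort, fit, m)
#> Balance over 11 covariate levels (122 matched pairs): mean SMD 0.671 pre, 0.015 post
```

The match keeps only the region of propensity overlap (122 of 500
treated), and the mean SMD drops from 0.671 to 0.015 — far below the
0.1 negligibility convention. Downstream, on the matched cohort:

```r
matched <- matched_cohort(cohort, m)
by_arm  <- split(matched, matched$arm)
t22 <- two_by_two(sum(by_arm$vats$recurrence), nrow(by_arm$vats),
                  sum(by_arm$chest_tube$recurrence), nrow(by_arm$chest_tube))
effect_summary(t22)[, c("rate_treated", "rate_control", "arr", "nnt")]
#>   rate_treated rate_control   arr   nnt
#> 1       0.0820        0.352 0.270  3.70

cox_fit(matched$time_months, matched$recurrence, matched$arm == "vats")
#> Cox fit (breslow ties): HR 0.198 (95% CI 0.099-0.394), log HR -1.6211 (SE 0.3513)
```

The matched recurrence rates (8.2% vs 35.2%) give an absolute risk
reduction of 27 points — one recurrence prevented per 3.7 surgical
patients — and the Cox hazard ratio of 0.198 brackets the generating
value 0.166 well inside its confidence interval. The economics:

```r
dc  <- mean(by_arm$vats$total_cost_cny) - mean(by_arm$chest_tube$total_cost_cny)
eff <- cohort_effects(matched)
dq  <- eff$qalys[eff$arm == "vats"] - eff$qalys[eff$arm == "chest_tube"]
cea <- compute_cea(dc, nrow(m$pairs), t22, dq)
tidy(cea)
#>   metric                                value
#> 1 delta_cost_per_patient            16605.
#> 2 delta_cost_cohort               2025769.
#> 3 delta_qaly_cohort                     5.06
#> ...
#> 6 icer_per_qaly                    399955.
#> 7 icer_per_recurrence               61387.

psa <- run_psa(psa_base_inputs(dc, nrow(m$pairs), t22),
               psa_config(n_iterations = 10000, seed = 101))
psa
#> PSA: 10000 iterations (0 faulted); quadrants NE 10000 / NW 0 / SE 0 / SW 0
#> P(cost-effective): 0.0918 at 1x GDP, 0.2429 at 3x GDP
```

VATS costs ¥16,605 more per patient and buys 5.06 cohort QALYs over 122
pairs (≈ 0.041 per pair under the default accrual model), an ICER of
¥399,955/QALY — above the 3× GDP threshold for this synthetic cohort —
with every PSA iteration in the north-east quadrant (more effective,
more costly). `plot_km()`, `autoplot()` on the balance report,
`plot_ce_plane()` and `plot_ceac()` render the standard figures, and
`one_way_scenarios()` produces the one-way sensitivity table.

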