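---
title: "Methods: matched-cohort effectiveness and cost-effectiveness analysis for first-episode pneumothorax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort effectiveness and cost-effectiveness analysis for first-episode pneumothorax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumocea)
```

## The analytical problem

First-episode primary spontaneous pneumothorax (PSP) with CT-confirmed
blebs can be managed with chest tube drainage or immediate
video-assisted thoracoscopic surgery (VATS, bullectomy with
pleurodesis). Drainage is cheaper up front but roughly half of
conservatively managed patients with blebs recur within five years,
while VATS removes the structural substrate at a higher initial cost.
Deciding between the strategies is therefore a joint
comparative-effectiveness and cost-effectiveness question: does the
recurrence reduction justify the incremental cost per quality-adjusted
life-year (QALY)?

`pneumocea` implements that full analysis as a reusable, testable
pipeline for retrospective treatment cohorts: propensity-score caliper
matching with balance diagnostics, recurrence and time-to-event effect
measures, a utility-based QALY decision model with discounting,
incremental cost-effectiveness ratios (ICERs) against willingness-to-pay
(WTP) thresholds, deterministic one-way scenario analysis, and
probabilistic sensitivity analysis (PSA) with cost-effectiveness plane
and acceptability-curve outputs. Because patient-level data from such
studies are generally not deposited, the package also ships a synthetic
cohort generator calibrated to the published baseline table of a
propensity-matched PSP cohort, so every stage can be exercised and
tested end to end without any external download.

## The synthetic cohort generator

`generate_cohort()` draws, per treatment arm, the seven baseline
covariates used throughout (sex; an age-at-45 indicator plus a
continuous age; smoking; laterality; degree of lung collapse, 30–50%
vs > 50%; maximum bleb diameter, < 1 cm / 1–5 cm / > 5 cm; bleb count,
1–2 / 3–5 / > 5), a recurrence process, and cost / length-of-stay
marginals.

**Confounded assignment.** The default per-arm category probabilities
are the exact count fractions of the pre-matching arms of the
calibration cohort (57 drainage vs 188 VATS patients), so treatment
assignment is strongly confounded: younger never-smokers with small,
few blebs preferentially received surgery. A scalar
`confounding_multiplier` exposes the assignment mechanism as a dial:
per covariate category the two arms sample from
`softmax(log g ± m/2 · δ)`, where `g` is the normalized geometric mean
of the two configured arm marginals and `δ` their per-category
log-ratio. At `m = 1` each arm reproduces its configured marginal
exactly; at `m = 0` the arms are exchangeable and every standardized
mean difference converges to zero; larger `m` is more confounded. This
single mechanism reconciles "marginals per arm" with "a tunable
confounding strength" without a copula: covariates are sampled
independently within arm because only marginal distributions are
available for calibration.

**Recurrence.** Times follow an exponential proportional-hazards law —
constant monthly hazard in the drainage arm, multiplied by
`exp(true_log_hr)` under VATS — administratively censored at the
60-month follow-up horizon. The default drainage hazard,
`-log(1 - 26/57)/60 ≈ 0.0102` per month, reproduces the calibration
cohort's 45.6% five-year recurrence; the default log hazard ratio is
`log(0.166)`. The exponential law is the minimal model consistent with
a single published hazard ratio; we deliberately do not model
time-varying hazards, repeat recurrences, or contralateral events.
Non-recurrent patients are censored exactly at 60 months, which also
reproduces the characteristic "median recurrence-free time not reached"
pattern in the surgical arm.

**Costs and stay.** Total cost is log-normal per arm, with `meanlog`
set to the log of the published post-match medians (¥26,922 VATS,
¥6,256 drainage) and `sdlog` derived from the published IQRs
(`log(q75/q25) / (2 Φ⁻¹(0.75))`). Recurrence in the drainage arm adds
a configurable management cost (default ¥5,000, on the order of one
drainage admission). Prolonged air leak occurs in a configurable subset
of drainage-arm complications and triggers crossover to rescue VATS
with probability 0.6 (3 of 5 such patients in the calibration cohort);
crossover adds a VATS-scale cost draw but never changes the arm label —
the intention-to-treat convention is fixed throughout the package.
Continuous age is drawn uniformly within the sampled age stratum
(18–45 / 45–75), which reproduces the stratum fractions exactly and the
published medians approximately; only the binary indicator enters the
propensity model.

**What the generator does not emulate.** Covariate dependence (only
marginals are calibrated), non-exponential recurrence dynamics,
within-pair cost correlation, site effects, and measurement error.
Tests that pass on these cohorts therefore validate the *estimators*
(bias, calibration, invariants) under a known truth — they do not
certify performance on real registry data with correlated covariates.

## Propensity matching and balance

`fit_propensity()` is a logistic regression of treatment (VATS = 1) on
the seven covariates, with the three-level bleb covariates dummy-coded
against their first level. Age enters as the binary ≥ 45 indicator
because the balance reporting convention stratifies age at 45; the
matching results are then directly comparable with the balance table.
Constant covariates are dropped to keep the design full rank; fitted
propensities within 1e-10 of 0 or 1 raise a separation error naming the
offending covariate pattern rather than returning an unusable fit.

`match_greedy()` performs 1:1 nearest-neighbor matching on the
propensity logit without replacement. The caliper defaults to 0.02
standard deviations of the logit (`caliper_mode = "sd_scaled"`), the
stricter of the two readings of a "0.02 caliper"; an absolute-width
mode is provided because the convention is ambiguous in much of the
applied literature. Ties between equally near controls break toward the
smaller control id, making results fully deterministic.

Treated units are processed in **data order** by default. We evaluated
descending-propensity processing (a common textbook suggestion) on
calibrated cohorts and found it systematically worsens post-match
covariate balance at identical pair counts: the sparse high-propensity
tail is matched first, and its within-caliper score gaps are
directionally biased. Data order — also the default in the standard
matching software in this field — avoids that artifact; descending and
seeded-random orders remain available via `order_rule`.

`balance_report()` reports one-vs-rest standardized mean differences
(SMDs) for eleven covariate levels: one level per binary covariate
(both levels of a binary covariate have identical SMDs) and every level
of the two three-level covariates. The mean SMD is the unweighted mean
over those eleven levels, with continuous age excluded and the ≥ 45
indicator included; this averaging set reproduces, on the calibration
cohort's published per-level SMDs, its published pre-match mean. Binary
SMDs use `|p_a − p_b| / sqrt((p_a(1−p_a) + p_b(1−p_b))/2)`; a zero
pooled variance with a non-zero difference is an error, and an empty
match reports post-match SMDs as `NA`, never as zero.

## Outcome statistics

- `effect_summary()` keeps rates, absolute risk reduction
  (ARR = control − treated), number needed to treat (NNT = 1/ARR) and
  relative risk at full precision, with presentation rounding (one
  decimal for percentages, two for NNT) in separate columns. A
  non-positive ARR reports NNT as infinite with a sign flag, never an
  exception.
- `mcnemar_test()` implements the exact test directly —
  `min(1, 2 P(X ≤ min(b,c)))` with `X ~ Binomial(b+c, 1/2)` — plus the
  continuity-corrected chi-square form; `b + c = 0` returns p = 1 with
  a degeneracy flag.
- Kaplan–Meier, log-rank and Cox fits delegate to the `survival`
  package behind stable wrappers (`km_fit()`, `logrank_test()`,
  `cox_fit()`), and the test suite validates each against independent
  oracles (hand product-limit computation, a term-by-term
  hypergeometric O−E sum, and golden-section maximization of the
  explicitly summed Breslow partial likelihood). Ties default to
  Breslow — the simplest form and the one matched by closed-form
  oracles — with Efron selectable; median confidence intervals use the
  log–log transform. Monotone partial likelihoods (all events in one
  arm before any in the other) raise a divergence error with a
  diagnostic instead of returning a huge coefficient.
- `sample_size_two_props()` provides both the pooled and unpooled
  normal-approximation variants, since published per-group requirements
  rarely state which was used (for the calibration cohort's anticipated
  rates of 45.6% vs 11.7% at α = 0.05 and 80% power, unpooled gives 24
  and pooled 27 per group); `inflate_sample_size()` applies an
  attrition factor with ceiling, and `power_two_props()` closes the
  loop so the returned n can be verified to achieve its nominal power.

## The QALY decision model

`qaly_trajectory()` integrates a piecewise-constant utility path over
the 60-month horizon. Default utilities are 1.0 (stable), 0.7 (active
pneumothorax episode) and 0.95 (post-recovery after a recurrence), with
14-day initial and recurrence episodes — values from published
cost-utility work on pneumothorax, since retrospective cohorts carry no
patient-reported utilities. Never-recurrent patients return to stable
health after the initial episode; post-recovery utility applies only
after a recurrence episode. That mapping is the minimal consistent
reading of a three-state utility set and is fully configurable.

Discounting is continuous-time by default, `∫ u(t) e^(−ρt) dt` with
`ρ = log(1 + annual rate)` and time in years. Continuous discounting
admits exact closed-form segment integrals, which is what makes the
1e-8 quadrature oracle in the test suite meaningful; an annual-cycle
accrual (`(1+r)^−year` weights per calendar-year slice) is available as
a switch for comparability with spreadsheet models. Episodes that would
extend past the horizon are truncated there and flagged. Costs are not
discounted by default: in this decision problem essentially all
intervention cost falls at time zero, and recurrence-management cost is
a configurable add-on.

One caution documented rather than hidden: published cohort-level QALY
gains for this comparison are not reconstructible from the stated
utilities and episode durations alone (a 14-day 0.3-utility decrement
per avoided recurrence is an order of magnitude too small), so the
package never treats any published ΔQALY as a validation target.
`compute_cea()` accepts the cohort ΔQALY as an explicit input, and the
internal model (`cohort_effects()` / the PSA's ΔQALY engine) derives it
from its own stated accrual assumptions. The per-recurrence ICER
supports an `arr_digits` option reproducing rounded-ARR presentation
arithmetic (0.364 rather than 12/33), because published per-recurrence
ICERs are computed from the rounded ARR.

## Scenario analysis and PSA

`one_way_scenarios()` re-evaluates the deterministic model with one
override at a time (pneumothorax utility 0.5/0.8, recurrence duration
7/21 days, cost ± 20%, discount 0/3/6% in the default grid), and can
attach a probability of cost-effectiveness from a PSA re-run with the
override held fixed.

`run_psa()` propagates parameter uncertainty by Monte Carlo
(default 10,000 iterations): utilities as beta distributions
(method-of-moments, default SE = 10% of the mean), incremental cost as
gamma (default SE = 20% of the mean), and per-arm recurrence
probabilities as beta with shapes (events + 1, non-events + 1) — the
conjugate-style defaults of standard PSA practice, used because the
calibration study's own distributional appendix is not public. Each
parameter owns a named random substream derived from the seed, so
adding a parameter never perturbs the others' draws, and `se = 0`
degenerates a distribution to its mean (the base case is then
reproduced bit-exactly — a property the acceptance tests assert). The
representative recurrence time for the PSA's QALY engine is the mean
observed recurrence time of the matched drainage arm (15 months in the
calibration data). Decisions use net monetary benefit
(`λ·ΔQALY − ΔCost > 0`, ties counted as not cost-effective) rather than
ratio comparisons, avoiding sign pathologies off the north-east
quadrant; faulted (non-finite) iterations are excluded and counted,
never silently dropped. Published acceptability probabilities for this
comparison depend on the unavailable appendix distributions, so the
package asserts the *structure* of the PSA (quadrant conservation, CEAC
monotonicity, threshold consistency, degenerate collapse) rather than
any specific probability.

## Numerical conventions and degenerate inputs

- Quantiles: linear interpolation between order statistics (R type 7),
  recorded in output metadata.
- Probability vectors must sum to 1 within 1e-12; configuration errors
  name the offending covariate or parameter.
- Seeds: every stochastic entry point takes an explicit integer seed;
  `run_pipeline()` fans a single run seed out to per-stage substreams
  keyed by stage name, so identical config + seed gives a byte-identical
  artifact bundle.
- Monetary values are kept at full precision internally and rounded
  only in rendered reports.

## Problem sizes used by the test suite

The shipped tests exercise the estimators at sizes chosen to make
sampling noise negligible relative to the asserted tolerances while
keeping a full run in well under a minute: marginal calibration and the
confounding dial at 20,000–50,000 patients per arm; hazard-ratio
recovery over 100 replicates of 2,000 per arm (estimates within
[0.13, 0.21] for a generating ratio of 0.166 in at least 95% of
replicates); log-rank type-I error over 2,000 null replicates of 50 per
group; matching balance over 20 replicates of 500 per arm; and the PSA
at its full 10,000 iterations. Oracle equivalence checks (exhaustive
pairing, brute-force partial likelihood, quadrature, binomial-tail
summation) run on problems small enough for exact enumeration.

## Known limitations

Beyond the generator simplifications above: no optimal or
with-replacement matching and no IPTW weighting; a single binary
treatment covariate in the Cox wrapper (by design — residual adjustment
sets are out of scope); no lifetime extrapolation beyond the 60-month
horizon; no societal-perspective costs; no value-of-information
analysis; and no correlated PSA draws. These mirror the boundaries of
the study design the package operationalizes.
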