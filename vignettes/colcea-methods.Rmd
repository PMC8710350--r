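---
title: "Model structure, calibration and validation in colcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and validation in colcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colcea)
```

## The decision problem

`colcea` models the lifetime consequences of choosing one adjuvant
chemotherapy strategy for a cohort of 60-year-old patients with resected
stage III colon cancer treated in public hospitals of an upper-middle-income
health system. Six active regimens (FOLFOX and CAPOX for 3 or 6 months,
capecitabine for 6 months, FU/LV for 6 months) are compared with surgery
alone. The societal perspective counts direct medical costs and the
transport and lost-wage costs of the patient and one accompanying caregiver.
Health effects are disability-adjusted life-years (DALYs) averted relative
to no chemotherapy; the decision rule is net monetary benefit at a
willingness-to-pay (WTP) threshold anchored to GDP per capita
(I$13,006.56 per DALY averted).

## State space and transition structure

The Markov state space is `DiseaseFree`, a set of recurrence tunnel states,
and two absorbing death states (`DeathCRC`, colon-cancer death, and
`DeathOther`). Recurrence is assumed to be clinically detected distant
metastasis. Two kinds of time-dependence motivate the expanded enumeration:

* **Recurrence stratum.** Prognosis after recurrence depends on when the
  recurrence occurred relative to surgery. Transitions out of `DiseaseFree`
  during months 1–24 enter the `EARLY` stratum, months 25–36 `MID`, months
  37+ `LATE` (boundary months assigned to the earlier stratum).
* **Tunnel depth.** Post-recurrence mortality also depends on how long the
  patient has already survived in recurrence, so each stratum is replicated
  into `tunnel_depth` monthly states (default 60). Survival conditioning of
  this kind flattens after about five years, so the deepest tunnel state
  reuses the last mortality entry and self-loops; the depth is configurable.

Cycles are one month; the horizon is `12 × (85 − start_age)` months
(300 at the default start age of 60). Patients disease-free for more than
the cure month (96) can no longer recur; they remain exposed to background
mortality only. One third of recurrences are assumed liver-only and one
third of those undergo curative-intent hepatectomy: the model attaches the
hepatectomy's one-time cost and a one-time disability term to that 1/9
fraction of recurrence entries but does **not** give resected patients a
distinct survival trajectory, because the model's post-recurrence mortality
inputs are not stratified by resection status. Metastatic treatment is at
most two chemotherapy lines (defaults 6 + 6 months, configurable) followed
by best supportive care, with no biologic agents.

### Numerical conventions

* **Competing risks.** Marginal monthly probabilities leaving one state are
  combined by converting to rates (`r = −ln(1−p)`), summing, converting
  back, and apportioning the total exit probability by rate share. This
  keeps every row stochastic even for large marginals. Probability-1 causes
  carry infinite rates and take the whole share.
* **Age indexing.** Model month `m` (1-based, the month being completed)
  uses the life-table entry at age `floor(start_age + m/12)`. Month 300
  therefore reads age 85, whose annual probability is 1 by construction, so
  the cohort empties without a special case; remaining alive mass at that
  forced exit is assigned to `DeathOther` (the cause split is undefined at
  probability 1).
* **Annual to monthly.** Life-table probabilities convert as
  `1 − (1−p)^(1/12)` (constant hazard within the year).
* **Background mortality inside recurrence.** Applied as a competing risk in
  every alive state, not only while disease-free.
* **Half-cycle correction.** All accruals (costs, DALYs, survival) weight
  cycle `t` by the mean of the occupancy at its two boundaries — the
  trapezoidal approximation of continuous membership — and discount at the
  cycle midpoint, `(1 + r)^(−(m − 0.5)/12)`.
* **Tolerances.** Trace rows must sum to 1 within 1e-9 (the engine errors
  otherwise); all arithmetic is double precision.
* **Ties.** Strategies tied on effectiveness keep the cheaper on the
  frontier; exact (cost, effect) duplicates are both kept and flagged
  equivalent.

## Outcome accrual

**DALYs** are years of life lost (YLL) plus years lived with disability
(YLD) without age-weighting, on the utility scale where 0 is no disability
and 1 equals death from colon cancer. YLL accrues person-time in `DeathCRC`
at weight 1 from the death until the model horizon; `DeathOther` accrues
nothing. This within-model convention needs no external life-expectancy
reference and cancels exactly in the "DALYs averted" difference; it does
mean absolute DALY totals are horizon-referenced, which is why comparisons
are reported against the common no-chemotherapy comparator. YLD accrues the
disease-free and recurrence disability weights, plus transient
treatment-related adverse-event (TRAE) disability: each TRAE contributes
probability × weight × duration, spread uniformly over the treatment course
(the inputs give per-course event probabilities, not event timing).

**Costs** accrue per state: during the adjuvant course, the monthly regimen
components (drug, personnel, administration — which carries the
port-a-cath/infusion-pump burden for infusional regimens — antiemetics,
bloodwork), expected TRAE costs spread over the course, and per-visit
indirect costs at the strategy's visit rate (oral regimens need 1 visit per
cycle against 5 for infusional FU/LV; 8 total for CAPOX 6MO against 12 for
FOLFOX 6MO, scaled for the 3-month arms). Disease-free follow-up accrues
surveillance costs and indirect costs at the surveillance visit rate
(surveillance visits are assumed to incur indirect costs like treatment
visits). Recurrence months accrue the active line's drug cost, its expected
TRAE costs, and one indirect visit per month, then best supportive care.
All amounts are international dollars at the fixed conversion
ZAR 6.86 = I$1; `zar_to_intl()`/`intl_to_zar()` convert exactly.

## Calibration from digitized survival curves

Recurrence inputs enter as digitized Kaplan–Meier coordinates
(`km_curve()`). The default fit (`fit_survival_spline()`) is a monotone
Hyman-filtered cubic interpolant on log-survival: digitized points are
treated as exact, monotonicity is preserved by construction, and the fitted
curve is verified to pass within 0.5 percentage points of every input point
(configurable). A `"smooth"` alternative (smoothing spline plus isotonic
projection on a monthly grid) handles noisy digitizations; the spline
family is a configuration choice because the original fitting procedure is
not specified beyond "spline".

Monthly probabilities are the discrete hazards
`p(m) = (S(m) − S(m+1))/S(m)`. Beyond the digitized range the default tail
rule carries the last fitted monthly hazard forward to the cure month
(month 96); an exponential refit to the final 24 months is available. After
the cure month every recurrence probability is exactly zero.

`validate_against_trial()` measures the percentage-point deviation between
model disease-free survival at a landmark and a trial-reported rate. Two
conventions are offered because trial DFS counts non-cancer deaths as
events while the calibration targets the recurrence process: the default
renormalizes disease-free occupancy by the life-table background survival
(under the rate-share convention this recovers the generating recurrence
curve exactly), and `"df_including_death"` compares raw disease-free
occupancy. The package's own validation bar, enforced in the test suite, is
a landmark deviation below 1.5 percentage points for every calibrated
synthetic curve.

## Sensitivity and scenario analysis

One-way deterministic analysis (`one_way_dsa()`) re-runs the complete
analysis at each range endpoint and records the ICER of the runner-up
frontier strategy against the optimum — the quantity a tornado diagram
displays — and whether the recommended strategy changes. Curve-level
uncertainty is expressed as a multiplicative hazard factor per strategy
(`p → 1 − (1−p)^f`), which is also how the ±20% recurrence check and the
risk-stratified scenario are implemented.

The probabilistic analysis (`draw_parameter_set()`, `run_psa()`) uses
conventional distribution families: beta for probabilities and disability
weights, gamma for costs, log-normal (mean 1) hazard factors for recurrence
curves, parameterized by their base-case mean and a coefficient of
variation (default 0.2) because the original per-parameter distribution
table is not machine-readable; per-block coefficients can be overridden,
and zero variance reproduces the base case exactly. Draws are independent
across parameters — correlated uncertainty is out of scope and a stated
limitation. `ceac()` re-evaluates the stored (cost, effect) samples over a
WTP grid (default 25 points from half to three times GDP per capita)
without re-simulation.

The risk-stratified scenario (`run_scenario()`) restricts the comparison to
the four oxaliplatin doublets plus the comparator and scales every arm's
recurrence hazard by a low- or high-risk multiplier. The labels correspond
to the usual stage III risk strata (low: T1–3 N1; high: T4 and/or N2) but
the model consumes only the risk-specific recurrence inputs.

## The synthetic scenario: what it does and does not emulate

Because neither the trial curves nor the fee-schedule cost tables are
redistributable, all defaults come from `synthetic_scenario()`, chosen once
to be clinically and economically plausible rather than fitted to any
published result:

* Weibull-like recurrence (shape 0.9, gently decreasing hazard) with
  5-year recurrence-free survival ~45% without chemotherapy, 55–57% for
  single-agent fluoropyrimidines and 62–64.5% for oxaliplatin doublets;
  6-month FOLFOX slightly better than 3-month, 3-month CAPOX marginally
  better than 6-month.
* Post-recurrence monthly colon-cancer mortality starting at 0.05/0.042/
  0.034 for early/mid/late recurrence and decaying 1.5% per month in
  recurrence with a floor of 0.012 (median post-recurrence survival around
  1.5 years, consistent with a pre-biologic treatment era).
* A geometric life table (base 0.012 at 60, growth 1.09/year, forced to 1
  at 85) emulating the elevated background mortality of the setting.
* Cost magnitudes that reproduce the setting's key economic feature:
  metastatic treatment (I$1,600 and I$1,200 per month for the two lines) is
  far costlier than adjuvant therapy, so forgoing adjuvant chemotherapy is
  the costliest policy and is strongly dominated; the FOLFOX administration
  component uses the known course total of I$2,416.33; indirect-cost
  constants (I$6.03 transport, 8 h × I$2.52, two persons) are the setting's
  published values.

The generator does **not** emulate: censoring or digitization error in the
KM inputs (available separately via `generate_km_points(n_at_risk = ...)`),
correlation between cost and effectiveness parameters, non-proportional
hazard differences between arms, or resection-status-specific
post-recurrence survival. Passing tests therefore demonstrate that the
machinery is correct under realistic input shapes, not that the synthetic
numbers equal any published result.

## Validation strategy and problem sizes

The package validates itself along two independent routes:

1. **Closed forms** — constant-hazard survival, discount factors,
   trapezoidal person-time against analytic integrals, hand-computed
   competing-risk rows, and an exact identity: under the rate-share
   convention, disease-free occupancy factorizes into the recurrence and
   background survival curves, so renormalized model DFS recovers the
   generating curve to machine precision.
2. **A microsimulation oracle** — `microsim_oracle()` simulates individual
   monthly trajectories under the same transition probabilities
   (re-derived inline) and accrual rules, as exact multinomial state-count
   dynamics with batch-based standard errors. The test suite compares the
   cohort engine against the oracle on cost, DALYs, overall survival and
   clinical-state occupancies across 20 random synthetic parameter sets at
   200,000 individuals each. With ~380 simultaneous standardized
   comparisons, a correct engine's largest |z| is expected near 3.3, so
   the suite checks the calibration of the whole z-distribution (median
   |z| < 1.5, 3-SE exceedances at their nominal rate, none beyond 4.5)
   rather than gating each comparison at 3 SE — a stricter guard against
   systematic bias. Occupancies are compared at the clinical-state level
   (disease-free, recurrence strata, deaths) because individual deep
   tunnel states hold too few simulated individuals for the normal
   approximation behind an SE-based check.

Other suite scales, chosen to keep the full run under a few minutes on one
core: 1,000 random frontier instances against a brute-force dominance
oracle plus the NMB/ICER selection-rule equivalence; 1,000 random parameter
sets for probability conservation (at tunnel depth 24, since conservation
does not depend on depth); calibration round trips at three constant
hazards and all seven Weibull-like strategy curves; and a constructed
two-arm PSA whose optimal-strategy probability is 0.50 by design, checked
at 10,000 iterations.

## Known limitations

* Post-recurrence mortality is independent of the adjuvant regimen
  received, and hepatectomy confers cost and transient disability but no
  survival benefit — both inherited from the structure of the available
  inputs.
* PSA draws are independent across parameters.
* The YLL convention references the model horizon, not an external
  life-expectancy table (a config switch for the standard convention would
  change absolute DALYs but not DALYs averted).
* Absolute results shipped with the package are conditional on the
  synthetic scenario; analyses of real settings should supply their own
  digitized curves, life table and cost schedule via `read_config()`,
  `read_km_csv()` and `read_life_table_csv()`.
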