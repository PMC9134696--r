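---
title: "Capacity-to-pay CHE: methodology, design choices, and what the synthetic survey does and does not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity-to-pay CHE: methodology and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chequity)
library(dplyr)
```

## The statistic and its assumptions

Catastrophic health expenditure (CHE) under the capacity-to-pay approach
asks whether a household's out-of-pocket (OOP) medical spending is large
relative to its *non-subsistence* resources, not relative to raw income or
consumption. The chain, per household:

| quantity | definition | units |
|---|---|---|
| `food_share` | food / consumption expenditure | fraction |
| `eqsize` | `hhsize^beta` | equivalent adults |
| `eqfood` | food / eqsize | currency / eq. adult / month |
| `pl` | weighted mean `eqfood` over the 45–55 food-share band | currency / eq. adult / month |
| `se` | `pl * eqsize` | currency / month |
| `ctp` | `exp - se` if `se <= food`, else `exp - food` | currency / month |
| `oopctp` | `oop / ctp` | fraction |
| `cata` | `oopctp >= threshold` | 0/1 |

The approach assumes (i) all monetary fields sit on one common monthly,
deflated scale — `deflate_to_monthly()` enforces this before anything else
runs; (ii) the survey is large and heterogeneous enough that the middle of
its food-share distribution identifies a meaningful subsistence benchmark;
and (iii) consumption expenditure is a usable proxy for household resources
(the equity literature's usual argument for expenditure over income in
ageing populations, where transfers and dissaving decouple the two).

Every quantity is scale-equivariant or scale-invariant in the currency:
multiplying all monetary inputs by *c* scales `pl`, `se`, `ctp` by *c* and
leaves `food_share`, `oopctp`, and every flag unchanged. The test suite
asserts this exactly, because it is the property that makes the statistic
comparable across price levels once deflation is applied.

## Tunable parameters

* `beta = 0.56` (dimensionless): the equivalence-scale exponent, the WHO
  value estimated from household surveys in 59 countries. `beta = 1` turns
  equivalized size into raw size; `beta -> 0` removes the household-size
  adjustment entirely.
* `band = c(45, 55)` (percentiles): the food-share window defining the
  poverty line. Narrower bands track the median household more tightly but
  become fragile in small surveys.
* `threshold = 0.40` (fraction of capacity to pay): the CHE cutoff,
  boundary-inclusive (`oopctp = 0.40` *is* catastrophic).
* `weights` (non-negative): optional sampling weights, honoured in the
  poverty line and every incidence summary; the default is unit weights,
  matching analyses that do not apply the survey's design weights.
* weekly-to-monthly food conversion `(365.25 / 7) / 12`: average weeks per
  month; configurable in `deflate_to_monthly()` since conventions differ.

None of these is hard-coded; all flow through `run_che()` /
`pipeline_config()`.

## Numerical choices

* **Percentiles** are linear interpolations between order statistics
  (`stats::quantile` type 7). The band is *open* (`food45 < foodexp <
  food55`). In tiny or heavily tied surveys the open band can be empty; the
  documented fallback closes the bounds, and if even the closed band is
  empty the error names the band rather than guessing. With n below about
  ten, both bounds interpolate between the same pair of order statistics,
  so only tied shares can populate the band at all — single-household and
  toy surveys work through the fallback.
* **Degenerate capacity to pay**: `ctp <= 0` can occur when a household
  spends nearly everything on food. The burden share is then undefined
  (`NA`), and any positive OOP counts as catastrophic — the conservative
  convention for households already at or below subsistence; it is
  switchable (`degenerate_is_che = FALSE`).
* **Food above consumption** is not an error (real surveys contain such
  households); the record passes through flagged, and the two-branch `ctp`
  rule handles it.
* **Quintiles** rank per-capita consumption expenditure ascending and split
  into five groups whose sizes differ by at most one (the lower groups take
  the remainder, e.g. 12 households split 3/3/2/2/2); ties break on
  `household_id`, so assignment is invariant to input row order and to
  currency rescaling.
* **IRLS** stops when the largest score component falls below 1e-8 or the
  relative log-likelihood change falls below 1e-10 (cap: 100 iterations).
  Standard errors are the exact inverse observed information at the final
  estimate — note `glm` reports SEs from the weights of its *last IRLS
  step*, which differ in the fifth digit; the tests compare against the
  exact formula tightly and against `glm` loosely.
* **Separation and collinearity** are errors, not silent degradation: a
  diverging coefficient with pinned probabilities raises a separation
  error; a rank-deficient design names the collinear columns. In `vif()`
  terms, exact dependence reports an infinite VIF rather than an exception.
* **Hosmer–Lemeshow** sorts by fitted probability into ten near-equal
  groups; tied probabilities never straddle a boundary, so group sizes
  deviate from n/10 as needed; df = groups − 2 (the conventional χ²(8)).
* **VIF** is computed per dummy column (`1/(1 - R²)` from OLS on the other
  non-intercept columns) and aggregated per categorical term by maximum.
  Dummies of one unbalanced factor are structurally negatively correlated,
  so the max-aggregated value for a dominant-category factor (household
  size class in the default generator) sits near 4 even when the factors
  themselves are nearly independent; per-dummy values are always available
  in the `vif` component.

## Open design points and how they were resolved

* **Band ranking key.** Methodological write-ups are ambiguous about
  whether the 45–55 band is taken on the food-*share* ranking or on total
  expenditure. The WHO convention — ranking by food share — is the
  default; `rank_by = "expenditure"` switches the key for sensitivity
  analysis.
* **Poverty line population.** The poverty line is computed once on the
  full cleaned survey, not on the chronic-disease subsample analysed
  downstream: subsistence is a property of the population, not of the
  disease stratum.
* **Model population.** The risk-factor model is fitted on the
  chronic-disease subsample by default (`model_population = "chronic"`),
  mirroring the study design such models come from; `"all"` fits on the
  full cleaned sample.
* **Design spec.** The default design mirrors the multivariable model
  reported in that literature: age (numeric), region, economic quintile,
  size class, labour participation, member 65+, disabled member, two
  utilization flags, five disease indicators, insurance type — with the
  descriptive covariates (sex, marital status, residence, education,
  self-rated health) available behind `extended = TRUE` but excluded from
  the default fit. No univariable screening and no multiple-testing
  adjustment are applied anywhere, matching that reporting style.

## What the synthetic survey emulates — and what it does not

`generate_survey()` produces the pre-cleaning field layout of a
CHARLS-style ageing survey: weekly food spending, monthly consumption,
annual OOP split into outpatient/inpatient parts, reported household size,
householder demographics, insurance scheme, member-level answers to the 14
chronic-disease screening questions, utilization flags, and injected
missingness that exercises each deterministic imputation rule (missing OOP
totals always keep their parts; member rows always reflect true size;
missing food is unsupplementable and forces deletion).

The monetary mechanism is the package's own design. Consumption is
log-normal (`exp_log_mean = log(2500)`, `exp_log_sd = 0.7`: right-skewed,
with a median near 2500 currency units/month); the food share is
Beta(4, 6) (mean 0.40, the Engel-coefficient scale of middle-income
ageing households). OOP is zero-inflated (`oop_zero_prob = 0.25`) and
otherwise generated as a multiple of the household's own capacity to pay:

```
oop = threshold * ctp * exp(burden_scale * eta),
eta = base_log_odds + X' true_beta + logit(V),   V ~ Uniform(0, 1)
```

so `oop >= threshold * ctp` exactly when `eta >= 0`, and the downstream CHE
flag follows a logistic model whose coefficients are `true_beta` *exactly*
(whenever the conditional probability stays below `1 - oop_zero_prob`; the
constructor warns when configured effects can breach that cap). This is the
point of the design: a marginal OOP distribution with covariate scaling
would make the implied odds ratio of the flag an unknown function of every
other parameter, and parameter-recovery tests would have no exact truth to
recover. Here the generator remains mechanistic — covariates act through
utilization and the OOP magnitude, never directly on the flag — yet the
ground truth is known in closed form and `true_che_probability()` exposes
it as a Monte-Carlo oracle.

Default effects are odds ratios familiar from multivariable CHE models
(inpatient use 2.73, outpatient use 2.16, member 65+ 1.43, disabled member
1.28, employee/resident insurance 0.49–0.56, other insurance 0.45, central
and western region 0.77–0.78); `base_log_odds = -1.45` puts the marginal
incidence near 23–27%, the scale reported for chronic-disease subsamples.
Covariate prevalences are illustrative marginals on that literature's
scale; the 14 per-condition prevalences are set so about half of
households screen chronic — real surveys reach that share with higher
per-condition prevalence because conditions cluster within people, which
the independent draws here do not model.

What passing tests therefore show: the chain computes the WHO statistic
correctly on any tabular input; the cleaning rules, tables and diagnostics
behave as specified; and the estimation machinery recovers known effects at
survey scale. What they do not show: anything about the *numerical* CHE
incidence or odds ratios of any real population — the generator is not
calibrated to CHARLS marginals, CPI series, joint covariate dependence, or
the correlation structure of real spending data.

## Problem sizes

The test suite runs the oracle-equivalence comparison on 1,000 random toy
households; parameter recovery on 50 replicates of 20,000-household
surveys (fitting on the roughly 10,000-household chronic subsample of
each); Hosmer–Lemeshow calibration on 500 replicates at n = 2,000 (the
rejection rate at α = 0.05 must land in [0.02, 0.08]); and pipeline
determinism at n = 600–800. `scripts/acceptance.R` reports the headline
quantities from one 20,000-household run. These sizes were chosen to make
Monte-Carlo error comfortably smaller than the tolerances being asserted.

## Known limitations

* Only the capacity-to-pay CHE definition is implemented — no
  share-of-income variants, normative food baskets, or impoverishment
  ("medical poverty") measures.
* Imputation is limited to the deterministic supplement rules
  (OOP = outpatient + inpatient; size = member-row count); no multiple
  imputation.
* Variance estimation ignores survey design (no clustering/stratification
  corrections); weights enter point estimates only.
* Wald intervals, not profile likelihood; for rare categories at moderate n
  the difference can matter.
* The generator draws covariates independently (apart from the
  age / member-65+ and chronic / utilization links), so collinearity
  patterns of real surveys are only partially represented.
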