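# chequity

Catastrophic health expenditure (CHE) analysis for household surveys, in R.

When a household's out-of-pocket (OOP) medical spending eats a large share of
what it can actually afford to spend beyond subsistence, that spending is
*catastrophic*: the family is trading food, schooling or assets for care.
The incidence of CHE and its risk factors — who gets hit, under which
insurance scheme, at which wealth level — are standard currency in
health-financing equity research. `chequity` implements the WHO
capacity-to-pay methodology for flagging CHE, together with the full analysis
chain such studies run around it: survey cleaning with deterministic
imputation rules and an exclusion log, chronic-disease household flagging
from the 14 screening questions used in ageing surveys, per-capita
expenditure quintiles, stratified incidence tables with Pearson chi-square
comparisons, and a multivariable logistic model of CHE risk with odds
ratios, Wald intervals, variance inflation factors and the Hosmer–Lemeshow
goodness-of-fit test.

Because the household microdata such studies use (e.g. the CHARLS panel) is
restricted, the package ships a mechanistic synthetic-survey generator with
known ground truth, so every stage — and the package itself — is testable
end to end without any data download.

## The method

For each household *h* with monthly food expenditure *food*, consumption
expenditure *exp*, OOP health spending *oop* and size *hhsize* (all deflated
to a common monthly scale):

1. food share: `foodexp = food / exp`
2. equivalized size: `eqsize = hhsize^β`, with β = 0.56 (WHO estimate from
   household surveys in 59 countries)
3. equivalized food spending: `eqfood = food / eqsize`
4. poverty line: `pl = Σ w·eqfood / Σ w` over households whose food share
   lies strictly between the 45th and 55th percentiles of the food-share
   distribution — a survey-internal subsistence benchmark per equivalent
   adult
5. subsistence expenditure: `se = pl · eqsize`
6. capacity to pay: `ctp = exp − se` if `se ≤ food`, else `ctp = exp − food`
7. OOP burden: `oopctp = oop / ctp`
8. CHE flag: `cata = 1` iff `oopctp ≥ 0.40` (boundary inclusive)

Risk factors are then estimated with a binary logistic model
`logit P(cata = 1) = β₀ + β'X` over the householder's demographics, region,
economic quintile, household composition, utilization, chronic-disease
indicators and insurance scheme, reported as odds ratios with 95% Wald
intervals. The fitting (iteratively reweighted least squares), the
Hosmer–Lemeshow decile test and the VIF collinearity diagnostics are
implemented in the package, not delegated — they are part of what it exists
to provide — and are cross-checked in the test suite against independent
implementations (`glm`, `chisq.test`, `car::vif`, brute-force oracles).

## Worked example

```r
library(chequity)
library(dplyr)

cfg <- synthetic_config(n_households = 4000, seed = 42)
survey <- generate_survey(cfg)

raw <- deflate_to_monthly(survey)            # weekly food, annual OOP -> monthly
households <- clean_records(raw) |>          # impute, exclude, log
  left_join(flag_chronic_household(raw$members), by = "household_id") |>
  assign_economic_quintile()

exclusion_log(households)
#> # A tibble: 5 × 4
#>   rule                       affected removed remaining
#>   <chr>                         <int>   <int>     <int>
#> 1 impute_oop_from_parts           189       0      4000
#> 2 impute_hhsize_from_members       81       0      4000
#> 3 drop_missing_food                84      84      3916
#> 4 drop_unresolved_hhsize            0       0      3916
#> 5 flag_food_exceeds_exp             0       0      3916

che <- run_che(households)
che
#> <che_survey> 3916 households
#>   poverty line: 871.5613 per equivalent adult (band 45-55, rank by food_share)
#>   beta = 0.56, threshold = 0.4
#>   CHE incidence: 27.07%
```

84 of 4000 generated households had food expenditure that could not be
supplemented and were deleted; the rest flow through the chain. The poverty
line (872 currency units per equivalent adult per month) anchors subsistence
spending; 27% of the remaining households spend at least 40% of their
capacity to pay out of pocket.

```r
hh <- left_join(households, tidy(che), by = "household_id")
incidence_table(filter(hh, chronic_household), "insurance")
#> CHE incidence by insurance (across strata)
#> # A tibble: 5 × 4
#>   stratum     n n_che incidence
#> 1 NRCMS    1282   382      29.8
#> 2 Other     116    24      20.7
#> 3 UEBMI     316    61      19.3
#> 4 URBMI     102    29      28.4
#> 5 URRBMI    233    79      33.9
#> chi-square = 20.9903, df = 4, p = 0.0003181

fit <- fit_che_model(filter(hh, chronic_household))
glance(fit)
#> # A tibble: 1 × 8
#>       n log_likelihood converged n_iter hl_statistic hl_df  hl_p max_vif
#> 1  2049         -1107. TRUE           5         11.2     8 0.193    4.31
```

Incidence is highest under the resident schemes and lowest under employee
insurance, and the chi-square comparison rejects homogeneity — the pattern
the generator's ground-truth insurance effects encode. In the fitted model,
inpatient use in the past year carries an odds ratio of 2.98 (95% CI
2.42–3.67) against a configured true effect of 2.73, and the
Hosmer–Lemeshow test (χ²(8) = 11.2, p = 0.19) does not reject the model's
calibration. `tidy(fit)` returns the full odds-ratio table;
`autoplot(fit)` draws it as a forest plot. `run_pipeline(pipeline_config(...))`
executes the whole chain in one call and writes a deterministic report
bundle (CSV tables + JSON diagnostics and manifest).

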