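Package: chequity
Title: Catastrophic Health Expenditure Analysis for Household Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the WHO capacity-to-pay methodology for flagging
    catastrophic health expenditure (CHE) in household survey data: food-share
    based poverty line, equivalence-scale subsistence expenditure, capacity to
    pay, and the 40 percent out-of-pocket burden threshold. Provides the
    surrounding analysis chain used in health-financing equity studies --
    survey cleaning with deterministic imputation and an exclusion log,
    chronic-disease household flagging, per-capita expenditure quintiles,
    stratified incidence tables with Pearson chi-square comparisons, and a
    multivariable logistic model of CHE risk with odds ratios, Wald intervals,
    variance inflation factors and the Hosmer-Lemeshow goodness-of-fit test.
    A mechanistic synthetic household-survey generator with known ground-truth
    effects makes the whole pipeline testable without restricted survey
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
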