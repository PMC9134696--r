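test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_households = 0), "n_households")
  expect_error(synthetic_config(oop_zero_prob = 1.5), "oop_zero_prob")
  expect_error(synthetic_config(burden_scale = -1), "burden_scale")
  expect_error(synthetic_config(household_size_probs = c(`1` = 0.5, `2` = 0.6)),
               "household_size_probs")
  expect_error(synthetic_config(true_beta = c(not_a_term = 1)), "not_a_term")
  expect_warning(synthetic_config(base_log_odds = 5),
                 "exceeds 1 - oop_zero_prob")
})

test_that("identical config and seed yield an identical survey", {
  cfg <- synthetic_config(n_households = 100, seed = 7)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(s1$households, s2$households)
  expect_identical(s1$members, s2$members)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero-OOP probability one silences all spending and all CHE", {
  cfg <- synthetic_config(n_households = 120, seed = 3, oop_zero_prob = 1,
                          missing_rates = c(food = 0, oop_total = 0, hhsize = 0))
  s <- generate_survey(cfg)
  expect_true(all(s$households$oop_annual == 0))
  cl <- clean_records(deflate_to_monthly(s))
  out <- run_che(cl)
  expect_equal(out$incidence, 0)
  expect_true(all(out$results$cata == 0L))
})

test_that("every household has at least one member row, sizes consistent", {
  s <- generate_survey(synthetic_config(n_households = 150, seed = 21))
  counts <- dplyr::count(s$members, household_id)
  expect_setequal(counts$household_id, s$households$household_id)
  # reported size, where present, equals the member-row count
  hh <- dplyr::left_join(s$households, counts, by = "household_id")
  ok <- !is.na(hh$hhsize)
  expect_equal(hh$hhsize[ok], hh$n[ok])
  expect_equal(sum(s$members$is_householder), 150)
})

test_that("missingness is explicit and the OOP parts always allow imputation", {
  cfg <- synthetic_config(n_households = 1500, seed = 5,
                          missing_rates = c(food = 0.1, oop_total = 0.1, hhsize = 0.1))
  s <- generate_survey(cfg)
  hh <- s$households
  expect_gt(sum(is.na(hh$food_weekly)), 0)
  expect_gt(sum(is.na(hh$hhsize)), 0)
  blanked <- is.na(hh$oop_annual)
  expect_gt(sum(blanked), 0)
  expect_true(all(!is.na(hh$oop_outpatient_annual[blanked])))
  expect_true(all(!is.na(hh$oop_inpatient_annual[blanked])))
  # parts sum to the (pre-blanking) total for observed households
  obs <- !blanked
  expect_equal(hh$oop_annual[obs],
               hh$oop_outpatient_annual[obs] + hh$oop_inpatient_annual[obs],
               tolerance = 1e-12)
})

test_that("shifting the expenditure location scales every monetary field", {
  cfg1 <- synthetic_config(n_households = 300, seed = 13)
  cfg2 <- synthetic_config(n_households = 300, seed = 13,
                           exp_log_mean = cfg1$exp_log_mean + log(1000))
  h1 <- generate_survey(cfg1)$households
  h2 <- generate_survey(cfg2)$households
  for (col in c("exp_month", "food_weekly", "oop_annual",
                "oop_outpatient_annual", "oop_inpatient_annual")) {
    ok <- !is.na(h1[[col]])
    expect_equal(h2[[col]][ok], 1000 * h1[[col]][ok], tolerance = 1e-9)
  }
  # and the CHE flags are untouched
  expect_identical(generate_survey(cfg1)$truth$cata_true,
                   generate_survey(cfg2)$truth$cata_true)
})

test_that("food share draws match the Beta moment", {
  cfg <- synthetic_config(n_households = 5000, seed = 1)
  s <- generate_survey(cfg)
  hh <- s$households
  fs <- (hh$food_weekly * (365.25 / 7) / 12) / hh$exp_month
  fs <- fs[!is.na(fs)]
  a <- cfg$food_share_alpha; b <- cfg$food_share_beta
  mu <- a / (a + b)
  se3 <- 3 * sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - mu), se3)
})

test_that("downstream CHE flags reproduce the generator's ground truth exactly", {
  cfg <- synthetic_config(n_households = 2000, seed = 17,
                          missing_rates = c(food = 0, oop_total = 0, hhsize = 0))
  s <- generate_survey(cfg)
  cl <- clean_records(deflate_to_monthly(s))
  out <- run_che(cl, beta = cfg$beta, band = cfg$band, threshold = cfg$threshold)
  truth <- s$truth[match(out$results$household_id, s$truth$household_id), ]
  expect_identical(out$results$cata, truth$cata_true)
  expect_equal(out$pl, truth$pl_internal[1], tolerance = 1e-9)
})

test_that("true_che_probability matches the latent model and is monotone", {
  cfg <- synthetic_config(n_households = 10, seed = 2)
  p_ref <- true_che_probability(cfg, n_draws = 1e5)
  p_inp <- true_che_probability(cfg, list(inpatient_year = "Yes"), n_draws = 1e5)
  expect_gt(p_inp, p_ref) # positive log-odds effect raises the probability
  # closed form: P = min(plogis(lin), 1 - zero prob), within 2 MC standard errors
  closed <- plogis(cfg$base_log_odds + log(2.73))
  expect_lt(abs(p_inp - closed), 2 * sqrt(closed * (1 - closed) / 1e5))
  # reproducible under the same config
  expect_identical(p_inp, true_che_probability(cfg, list(inpatient_year = "Yes"), n_draws = 1e5))
  expect_error(true_che_probability(cfg, list(bogus = "Yes")), "bogus")
})

test_that("null effects make the CHE probability covariate-free", {
  cfg <- synthetic_config(n_households = 10, seed = 4, true_beta = numeric(0))
  profiles <- list(list(), list(inpatient_year = "Yes"),
                   list(region = "West", insurance = "UEBMI"))
  ps <- vapply(profiles, function(pr) true_che_probability(cfg, pr, n_draws = 2e5),
               numeric(1))
  expect_lt(max(ps) - min(ps), 4 * sqrt(0.25 / 2e5) * 2)
})

test_that("with all true effects zero the fitted odds ratios hover at one", {
  cfg <- synthetic_config(n_households = 6000, seed = 9, true_beta = numeric(0),
                          missing_rates = c(food = 0, oop_total = 0, hhsize = 0))
  s <- generate_survey(cfg)
  cl <- clean_records(deflate_to_monthly(s))
  cl <- dplyr::left_join(cl, flag_chronic_household(s$members), by = "household_id")
  cl <- assign_economic_quintile(cl)
  hh <- dplyr::left_join(cl, tidy(run_che(cl)), by = "household_id")
  fit <- fit_che_model(hh)
  tab <- dplyr::filter(tidy(fit), term %in%
                         c("inpatient_yearYes", "outpatient_monthYes",
                           "member_65plusYes", "insuranceUEBMI"))
  expect_true(all(abs(tab$estimate) < 3.5 * tab$std_error))
})

test_that("survey CSV round-trip preserves the tables", {
  s <- generate_survey(synthetic_config(n_households = 40, seed = 8))
  dir <- withr::local_tempdir()
  write_survey_csv(s, dir)
  r <- read_survey_csv(file.path(dir, "households.csv"),
                       file.path(dir, "members.csv"))
  expect_equal(dim(r$households), dim(s$households))
  expect_identical(names(r$households), names(s$households))
  for (col in c("exp_month", "food_weekly", "oop_annual", "age")) {
    expect_equal(as.numeric(r$households[[col]]), as.numeric(s$households[[col]]),
                 tolerance = 1e-12)
  }
  expect_identical(r$households$insurance, s$households$insurance)
  expect_equal(r$members$heart_disease, s$members$heart_disease)
})
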