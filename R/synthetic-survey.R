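#' Generate a synthetic household survey
#'
#' Draws a full pre-cleaning survey — a household-level table and a
#' member-level table — from a [synthetic_config()], with known ground truth
#' attached. The mechanism mirrors how out-of-pocket (OOP) spending produces
#' catastrophic health expenditure (CHE): covariates raise a latent burden on
#' the log-odds scale, the burden scales OOP as a multiple of the household's
#' capacity to pay, and the CHE flag emerges downstream from the usual
#' capacity-to-pay chain. Missingness is injected afterwards so that every
#' deterministic imputation rule of the cleaning stage is exercised.
#'
#' @details
#' Column dictionary, household table: `household_id`; `hhsize` (reported,
#' may be `NA`); `month` (interview month 1-12, for CPI deflation);
#' `food_weekly` (weekly food expenditure, may be `NA`); `exp_month` (monthly
#' consumption expenditure); `oop_annual` (annual OOP total, may be `NA`);
#' `oop_outpatient_annual`, `oop_inpatient_annual` (parts, always present and
#' summing to the total); `weight` (sampling weight, 1); householder
#' covariates `age`, `sex`, `marital`, `residence`, `education`, `region`,
#' `labour`, `srh`, `insurance`; household covariates `member_65plus`,
#' `disabled_member`, `outpatient_month`, `inpatient_year`.
#'
#' Member table: `household_id`, `member_id`, `is_householder`, and one
#' logical column per chronic-disease screening question (14 columns, named
#' as in [default_disease_prevalences()]). Member rows always reflect the
#' household's true size even when the reported `hhsize` is blanked, so size
#' imputation by family code recovers the truth.
#'
#' The `truth` component records, per household, the latent linear predictor
#' (`lin`), the exact model probability `p_true = min(plogis(lin),
#' 1 - oop_zero_prob)`, the zero-OOP indicator and the realized flag
#' `cata_true`; it is the oracle for parameter-recovery tests and is never
#' used by the analysis chain itself.
#'
#' @param config A [synthetic_config()].
#' @return A `raw_survey` object: list with tibbles `households`, `members`,
#'   `truth`, and the generating `config`.
#' @examples
#' s <- generate_survey(synthetic_config(n_households = 50, seed = 7))
#' s$households
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- validate_synthetic_config(config)
  n <- as.integer(config$n_households)
  seed <- config$seed
  prev <- config$covariate_prevalences
  household_id <- sprintf("hh%06d", seq_len(n))

  hhsize_true <- with_field_seed(seed, "hhsize",
    sample(1:6, n, replace = TRUE, prob = config$household_size_probs))
  age <- with_field_seed(seed, "age", pmin(pmax(round(rnorm(n, 62, 10)), 45), 100))
  month <- with_field_seed(seed, "month", sample(1:12, n, replace = TRUE))

  cat_draw <- function(field) {
    with_field_seed(seed, field, draw_categorical(n, prev[[field]]))
  }
  sex <- cat_draw("sex"); marital <- cat_draw("marital")
  residence <- cat_draw("residence"); education <- cat_draw("education")
  region <- cat_draw("region"); labour <- cat_draw("labour")
  srh <- cat_draw("srh"); insurance <- cat_draw("insurance")
  disabled_member <- cat_draw("disabled_member")

  member_65plus <- with_field_seed(seed, "member65", {
    extra <- hhsize_true > 1 & runif(n) < config$other_member_65_prob
    ifelse(age >= 65 | extra, "Yes", "No")
  })

  # householder chronic-disease answers (14 screening questions)
  dis_names <- names(config$disease_prevalences)
  head_dis <- with_field_seed(seed, "householder_disease", {
    m <- matrix(runif(n * 14), n, 14) <
      matrix(config$disease_prevalences, n, 14, byrow = TRUE)
    colnames(m) <- dis_names
    m
  })
  chronic_householder <- rowSums(head_dis) > 0

  # other members' answers, at scaled prevalences
  n_extra <- hhsize_true - 1L
  total_extra <- sum(n_extra)
  extra_dis <- with_field_seed(seed, "member_disease", {
    p <- config$member_disease_scale * config$disease_prevalences
    m <- matrix(runif(total_extra * 14), total_extra, 14) <
      matrix(p, total_extra, 14, byrow = TRUE)
    colnames(m) <- dis_names
    m
  })
  extra_hid <- rep(household_id, n_extra)
  extra_any <- rowSums(extra_dis) > 0
  chronic_household <- chronic_householder |
    household_id %in% unique(extra_hid[extra_any])

  # utilization: base prevalence lifted on the log-odds scale by chronic
  # illness and bad self-rated health of the householder
  util_lin <- function(base_yes) {
    qlogis(base_yes) + config$util_log_odds[["chronic"]] * chronic_householder +
      config$util_log_odds[["srh_bad"]] * (srh == "Bad")
  }
  outpatient_month <- with_field_seed(seed, "outpatient",
    ifelse(runif(n) < plogis(util_lin(prev$outpatient_month[["Yes"]])), "Yes", "No"))
  inpatient_year <- with_field_seed(seed, "inpatient",
    ifelse(runif(n) < plogis(util_lin(prev$inpatient_year[["Yes"]])), "Yes", "No"))

  exp_month <- with_field_seed(seed, "expenditure",
    rlnorm(n, config$exp_log_mean, config$exp_log_sd))
  fs <- with_field_seed(seed, "food_share",
    rbeta(n, config$food_share_alpha, config$food_share_beta))
  food_month <- fs * exp_month

  # analysis covariates derived exactly as the downstream chain derives them
  hh <- tibble(
    household_id = household_id, hhsize = hhsize_true, month = month,
    exp_month = exp_month, age = age, sex = sex, marital = marital,
    residence = residence, education = education, region = region,
    labour = labour, srh = srh, insurance = insurance,
    member_65plus = member_65plus, disabled_member = disabled_member,
    outpatient_month = outpatient_month, inpatient_year = inpatient_year
  )
  hh$size_class <- size_class_of(hhsize_true)
  hh$econ_level <- if (n >= 5) assign_economic_quintile(hh)$econ_level else factor(rep("1", n), levels = as.character(1:5))
  for (d in c("heart_disease", "stroke", "malignant_tumour",
              "chronic_lung_disease", "diabetes")) {
    hh[[d]] <- ifelse(head_dis[, d], "Yes", "No")
  }

  # latent burden: exact logistic structure for the downstream CHE flag
  X <- design_matrix_for(hh, che_design_spec(extended = TRUE))
  terms <- names(config$true_beta)
  lin <- config$base_log_odds +
    if (length(terms)) drop(X[, terms, drop = FALSE] %*% config$true_beta) else 0
  V <- with_field_seed(seed, "burden", runif(n))
  eta <- lin + qlogis(V)

  # internal capacity-to-pay chain (same functions the analysis uses)
  eqsize <- equivalized_size(hhsize_true, config$beta)
  chain <- tibble(food_share = fs, eqfood = food_month / eqsize)
  pl <- poverty_line(chain, band = config$band)
  se <- pl * eqsize
  ctp <- capacity_to_pay(exp_month, food_month, se)
  oop_month <- ifelse(V < config$oop_zero_prob, 0,
                      config$threshold * ctp * exp(config$burden_scale * eta))

  oop_annual <- 12 * oop_month
  inp_share <- with_field_seed(seed, "oop_split", {
    s <- numeric(n)
    both <- inpatient_year == "Yes" & outpatient_month == "Yes"
    inp_only <- inpatient_year == "Yes" & !both
    s[both] <- rbeta(sum(both), 2, 2)
    s[inp_only] <- rbeta(sum(inp_only), 6, 2)
    s
  })
  oop_inpatient_annual <- oop_annual * inp_share
  oop_outpatient_annual <- oop_annual - oop_inpatient_annual
  food_weekly <- food_month * 12 / (365.25 / 7)

  # missingness injection (after all values exist; never silently zero)
  rates <- config$missing_rates
  food_weekly[with_field_seed(seed, "missing_food", runif(n)) < rates[["food"]]] <- NA_real_
  oop_annual[with_field_seed(seed, "missing_oop", runif(n)) < rates[["oop_total"]]] <- NA_real_
  hhsize_rep <- hhsize_true
  hhsize_rep[with_field_seed(seed, "missing_hhsize", runif(n)) < rates[["hhsize"]]] <- NA_integer_

  households <- dplyr::mutate(
    hh[, c("household_id", "month", "age", "sex", "marital", "residence",
           "education", "region", "labour", "srh", "insurance",
           "member_65plus", "disabled_member", "outpatient_month",
           "inpatient_year")],
    hhsize = hhsize_rep, food_weekly = food_weekly, exp_month = exp_month,
    oop_annual = oop_annual, oop_outpatient_annual = oop_outpatient_annual,
    oop_inpatient_annual = oop_inpatient_annual, weight = 1,
    .after = "household_id"
  )

  members <- build_member_table(household_id, hhsize_true, head_dis, extra_dis, extra_hid)

  truth <- tibble(
    household_id = household_id, lin = lin,
    p_true = pmin(plogis(lin), 1 - config$oop_zero_prob),
    oop_zero = V < config$oop_zero_prob,
    cata_true = as.integer(V >= config$oop_zero_prob & eta >= 0),
    pl_internal = pl
  )

  structure(list(households = households, members = members,
                 truth = truth, config = config),
            class = "raw_survey")
}

size_class_of <- function(hhsize) {
  factor(ifelse(hhsize >= 3, "3plus", as.character(hhsize)),
         levels = c("1", "2", "3plus"))
}

build_member_table <- function(household_id, hhsize_true, head_dis, extra_dis, extra_hid) {
  n <- length(household_id)
  head_tbl <- as_tibble(head_dis)
  head_tbl <- dplyr::bind_cols(
    tibble(household_id = household_id, member_id = paste0(household_id, "_m1"),
           is_householder = TRUE),
    head_tbl
  )
  if (nrow(extra_dis) > 0) {
    idx <- sequence(hhsize_true - 1L) + 1L
    extra_tbl <- dplyr::bind_cols(
      tibble(household_id = extra_hid,
             member_id = paste0(extra_hid, "_m", idx),
             is_householder = FALSE),
      as_tibble(extra_dis)
    )
    out <- dplyr::bind_rows(head_tbl, extra_tbl)
  } else {
    out <- head_tbl
  }
  dplyr::arrange(out, .data$household_id, .data$member_id)
}

#' @export
print.raw_survey <- function(x, ...) {
  cat("<raw_survey> ", nrow(x$households), " households, ",
      nrow(x$members), " members\n", sep = "")
  if (!is.null(x$config)) cat("  generated with seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Generator-implied probability of catastrophic expenditure for a profile
#'
#' Monte-Carlo estimate of `P(cata = 1 | covariates)` under the generator's
#' monetary mechanism at a fixed covariate profile: the latent burden is
#' `base_log_odds + x'true_beta + logit(V)` and the flag fires when the
#' household is not a zero-OOP household and the burden is non-negative.
#' This is the oracle against which fitted odds ratios are judged in
#' recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param covariates Named list of covariate values overriding the reference
#'   profile (reference level of every categorical term, age 60). Names must
#'   be design columns of [che_design_spec()] (extended set).
#' @param n_draws Monte-Carlo draws. Default `1e5`.
#' @return A single probability.
#' @export
true_che_probability <- function(config, covariates = list(), n_draws = 1e5) {
  if (!inherits(config, "synthetic_config")) config <- validate_synthetic_config(config)
  spec <- che_design_spec(extended = TRUE)
  prof <- reference_profile(spec)
  unknown <- setdiff(names(covariates), names(prof))
  if (length(unknown)) {
    abort(paste0("Unknown covariate name(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(covariates)) prof[[nm]] <- covariates[[nm]]
  X <- design_matrix_for(prof, spec)
  lin <- config$base_log_odds +
    drop(X[, names(config$true_beta), drop = FALSE] %*% config$true_beta)
  V <- with_field_seed(config$seed, "true_che_probability", runif(n_draws))
  mean(V >= config$oop_zero_prob & lin + qlogis(V) >= 0)
}

# One-row tibble with every design column at its reference value.
reference_profile <- function(spec) {
  prof <- tibble(.rows = 1)
  for (i in seq_len(nrow(spec))) {
    col <- spec$column[i]
    if (spec$type[i] == "numeric") {
      prof[[col]] <- 60
    } else {
      prof[[col]] <- factor(spec$ref[i], levels = spec$levels[[i]])
    }
  }
  prof
}
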