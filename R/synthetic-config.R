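#' Configuration for the synthetic household-survey generator
#'
#' Bundles every knob of the generator: sample size, seed, monetary
#' distributions, covariate prevalences, and the ground-truth log-odds effects
#' through which covariates drive catastrophic health expenditure (CHE).
#'
#' @details
#' The generator emulates the household fields used by capacity-to-pay CHE
#' studies of middle-aged and older Chinese households: weekly food
#' expenditure, monthly consumption expenditure, annual out-of-pocket (OOP)
#' medical spending split into outpatient and inpatient parts, household size,
#' householder demographics, residence, region, insurance scheme, member-level
#' answers to the 14 chronic-disease screening questions, utilization flags,
#' disability, and presence of a member aged 65+.
#'
#' Monthly consumption is log-normal; the food share of consumption is
#' Beta-distributed; OOP is zero-inflated and otherwise generated
#' mechanistically as a multiple of the household's capacity to pay:
#' `oop = threshold * ctp * exp(burden_scale * eta)` with latent burden
#' `eta = base_log_odds + X'true_beta + logit(V)`, `V ~ Uniform(0,1)`, and
#' `oop = 0` when `V < oop_zero_prob`. Because `oop >= threshold * ctp`
#' exactly when `eta >= 0`, the CHE flag follows a logistic model whose
#' coefficients are `true_beta` — the generator-implied odds ratio of every
#' covariate is known exactly, which is what makes downstream parameter
#' recovery testable. This holds whenever the conditional CHE probability
#' stays below `1 - oop_zero_prob`; the constructor warns if the configured
#' effects can breach that cap.
#'
#' @param n_households Number of households to generate (`>= 1`).
#' @param seed Integer seed; the same `(config, seed)` always yields an
#'   identical survey. Each field draws from its own deterministic sub-stream,
#'   so adding fields to the generator does not perturb existing ones.
#' @param exp_log_mean,exp_log_sd Log-scale mean and sd of monthly household
#'   consumption expenditure (currency units).
#' @param food_share_alpha,food_share_beta Shape parameters of the Beta
#'   food-share distribution on (0, 1).
#' @param oop_zero_prob Probability a household has zero OOP spending.
#' @param base_log_odds Intercept of the latent CHE burden model (log-odds).
#' @param burden_scale Positive scale linking the latent burden to the OOP
#'   magnitude; affects the spread of burden shares, not the CHE flag.
#' @param true_beta Named vector of ground-truth log-odds effects on CHE.
#'   Names must be design-matrix dummy columns of the regression design (see
#'   [che_design_spec()]), e.g. `inpatient_yearYes`, `insuranceUEBMI`.
#' @param household_size_probs Named probability vector over sizes `1:6`.
#' @param covariate_prevalences Named list of category-probability vectors for
#'   the categorical covariates (`sex`, `marital`, `residence`, `education`,
#'   `region`, `labour`, `srh`, `insurance`, `disabled_member`,
#'   `outpatient_month`, `inpatient_year`). Utilization entries are base
#'   probabilities before the chronic/self-rated-health lift.
#' @param disease_prevalences Named length-14 vector of householder
#'   probabilities for the chronic-disease screening questions.
#' @param member_disease_scale Multiplier applied to `disease_prevalences` for
#'   non-householder members.
#' @param other_member_65_prob Probability a multi-person household has a
#'   member aged 65+ when the householder is younger than 65.
#' @param util_log_odds Named vector `c(chronic=, srh_bad=)`: log-odds lift of
#'   service utilization for chronically ill householders and those with bad
#'   self-rated health.
#' @param missing_rates Named vector `c(food=, oop_total=, hhsize=)` of
#'   missingness probabilities. When the annual OOP total is blanked, its
#'   outpatient and inpatient parts are kept, so downstream imputation can
#'   restore it.
#' @param beta,band,threshold CHE-chain parameters used inside the generator's
#'   monetary mechanism; keep in sync with the downstream analysis.
#' @return A validated `synthetic_config` object (a list).
#' @seealso [generate_survey()], [true_che_probability()]
#' @export
synthetic_config <- function(
    n_households = 2000,
    seed = 1L,
    exp_log_mean = log(2500),
    exp_log_sd = 0.7,
    food_share_alpha = 4,
    food_share_beta = 6,
    oop_zero_prob = 0.25,
    base_log_odds = -1.45,
    burden_scale = 0.5,
    true_beta = default_true_beta(),
    household_size_probs = c(`1` = 0.13, `2` = 0.55, `3` = 0.12,
                             `4` = 0.10, `5` = 0.06, `6` = 0.04),
    covariate_prevalences = default_covariate_prevalences(),
    disease_prevalences = default_disease_prevalences(),
    member_disease_scale = 0.6,
    other_member_65_prob = 0.25,
    util_log_odds = c(chronic = 0.8, srh_bad = 0.6),
    missing_rates = c(food = 0.02, oop_total = 0.05, hhsize = 0.02),
    beta = 0.56,
    band = c(45, 55),
    threshold = 0.4) {
  cfg <- list(
    n_households = n_households, seed = seed,
    exp_log_mean = exp_log_mean, exp_log_sd = exp_log_sd,
    food_share_alpha = food_share_alpha, food_share_beta = food_share_beta,
    oop_zero_prob = oop_zero_prob, base_log_odds = base_log_odds,
    burden_scale = burden_scale, true_beta = true_beta,
    household_size_probs = household_size_probs,
    covariate_prevalences = covariate_prevalences,
    disease_prevalences = disease_prevalences,
    member_disease_scale = member_disease_scale,
    other_member_65_prob = other_member_65_prob,
    util_log_odds = util_log_odds, missing_rates = missing_rates,
    beta = beta, band = band, threshold = threshold
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$n_households) != 1 || !is.finite(cfg$n_households) ||
      cfg$n_households < 1 || cfg$n_households != round(cfg$n_households)) {
    abort("`n_households` must be a positive integer.")
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed)) abort("`seed` must be a single integer.")
  if (!is.finite(cfg$exp_log_sd) || cfg$exp_log_sd < 0) abort("`exp_log_sd` must be >= 0.")
  if (cfg$food_share_alpha <= 0 || cfg$food_share_beta <= 0) {
    abort("`food_share_alpha` and `food_share_beta` must be positive.")
  }
  check_scalar_prob(cfg$oop_zero_prob, "oop_zero_prob")
  if (!is.finite(cfg$burden_scale) || cfg$burden_scale <= 0) {
    abort("`burden_scale` must be a positive number.")
  }
  check_prob_vector(cfg$household_size_probs, "household_size_probs")
  if (!identical(names(cfg$household_size_probs), as.character(1:6))) {
    abort("`household_size_probs` must be named '1'..'6'.")
  }
  for (nm in names(cfg$covariate_prevalences)) {
    check_prob_vector(cfg$covariate_prevalences[[nm]],
                      paste0("covariate_prevalences$", nm))
  }
  need_cov <- c("sex", "marital", "residence", "education", "region", "labour",
                "srh", "insurance", "disabled_member", "outpatient_month",
                "inpatient_year")
  miss <- setdiff(need_cov, names(cfg$covariate_prevalences))
  if (length(miss)) {
    abort(paste0("`covariate_prevalences` is missing: ", paste(miss, collapse = ", ")))
  }
  if (length(cfg$disease_prevalences) != 14 ||
      is.null(names(cfg$disease_prevalences))) {
    abort("`disease_prevalences` must be a named vector over the 14 chronic conditions.")
  }
  if (any(cfg$disease_prevalences < 0 | cfg$disease_prevalences > 1)) {
    abort("`disease_prevalences` must lie in [0, 1].")
  }
  check_scalar_prob(cfg$member_disease_scale, "member_disease_scale")
  check_scalar_prob(cfg$other_member_65_prob, "other_member_65_prob")
  for (nm in names(cfg$missing_rates)) {
    check_scalar_prob(cfg$missing_rates[[nm]], paste0("missing_rates$", nm))
  }
  bad <- setdiff(names(cfg$true_beta), design_dummy_names(che_design_spec(extended = TRUE)))
  if (length(bad)) {
    abort(paste0("`true_beta` names do not match any design-matrix term: ",
                 paste(bad, collapse = ", ")))
  }
  # cap check: exact logistic structure of the flag needs P(CHE|x) <= 1 - oop_zero_prob
  # (irrelevant in the degenerate all-zero-OOP world, where no CHE can occur)
  p_max <- plogis(cfg$base_log_odds + sum(pmax(cfg$true_beta, 0)))
  if (cfg$oop_zero_prob < 1 && p_max > 1 - cfg$oop_zero_prob + 1e-12) {
    warn(sprintf(paste0(
      "Worst-case conditional CHE probability (%.3f) exceeds 1 - oop_zero_prob (%.3f); ",
      "for such covariate profiles the flag probability is capped and true_beta is no ",
      "longer the exact log-odds effect."), p_max, 1 - cfg$oop_zero_prob))
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> n =", x$n_households, ", seed =", x$seed, "\n")
  cat("  exp ~ lognormal(", round(x$exp_log_mean, 3), ",", x$exp_log_sd,
      "); food share ~ Beta(", x$food_share_alpha, ",", x$food_share_beta, ")\n")
  cat("  oop_zero_prob =", x$oop_zero_prob, "; base_log_odds =", x$base_log_odds,
      "; burden_scale =", x$burden_scale, "\n")
  cat("  true effects (odds ratios):\n")
  print(round(exp(x$true_beta), 3))
  invisible(x)
}

#' Default ground-truth log-odds effects
#'
#' Effects on the latent CHE burden, on the odds-ratio scale familiar from
#' multivariable CHE models: inpatient use in the past year 2.73, outpatient
#' use in the past month 2.16, member aged 65+ 1.43, disabled member 1.28,
#' and protective insurance-scheme (UEBMI 0.49, URBMI 0.56, other 0.45) and
#' region (central 0.77, west 0.78) contrasts against the URRBMI / east
#' references.
#'
#' @return Named numeric vector of log-odds effects.
#' @export
default_true_beta <- function() {
  c(inpatient_yearYes  = log(2.73),
    outpatient_monthYes = log(2.16),
    member_65plusYes   = log(1.43),
    disabled_memberYes = log(1.28),
    insuranceUEBMI     = log(0.49),
    insuranceURBMI     = log(0.56),
    insuranceOther     = log(0.45),
    regionCentral      = log(0.77),
    regionWest         = log(0.78))
}

#' Default covariate prevalences
#'
#' Illustrative category probabilities on the scale reported for
#' chronic-disease household samples of middle-aged and older adults in China;
#' they set marginal frequencies only and are not calibrated to any survey's
#' joint distribution.
#'
#' @return Named list of probability vectors.
#' @export
default_covariate_prevalences <- function() {
  list(
    sex        = c(Male = 0.455, Female = 0.545),
    marital    = c(Married = 0.78, Single = 0.22),
    residence  = c(Rural = 0.70, Urban = 0.30),
    education  = c(Illiterate = 0.24, Primary = 0.435, JuniorOrAbove = 0.325),
    region     = c(East = 0.32, Central = 0.34, West = 0.34),
    labour     = c(No = 0.5, Yes = 0.5),
    srh        = c(Good = 0.63, Bad = 0.37),
    insurance  = c(URRBMI = 0.116, UEBMI = 0.152, NRCMS = 0.635,
                   URBMI = 0.047, Other = 0.050),
    disabled_member = c(No = 0.76, Yes = 0.24),
    outpatient_month = c(No = 0.83, Yes = 0.17),
    inpatient_year   = c(No = 0.82, Yes = 0.18)
  )
}

#' Default householder prevalences for the 14 chronic-disease questions
#'
#' Set so that, with conditions drawn independently, roughly a third of
#' householders and about half of households screen positive for at least one
#' condition — the subsample scale at which chronic-vs-none contrasts stay
#' informative. Real surveys reach a similar any-condition share with higher
#' per-condition prevalences because conditions cluster within people; the
#' independent draws here trade per-condition realism for a realistic
#' household-level share.
#'
#' @return Named length-14 probability vector.
#' @export
default_disease_prevalences <- function() {
  c(hypertension = 0.080, dyslipidaemia = 0.030, diabetes = 0.028,
    malignant_tumour = 0.008, chronic_lung_disease = 0.030,
    liver_disease = 0.010, heart_disease = 0.040, stroke = 0.028,
    kidney_disease = 0.015, digestive_disease = 0.040,
    emotional_problem = 0.005, memory_disease = 0.008,
    arthritis = 0.065, asthma = 0.010)
}
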