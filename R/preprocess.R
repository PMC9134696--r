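#' Deflate survey monetary fields to a common monthly scale
#'
#' Converts weekly food expenditure and annual out-of-pocket (OOP) spending to
#' monthly values, optionally deflating by a consumer price index (CPI)
#' factor: weekly food is multiplied by `(365.25 / 7) / 12` (average weeks per
#' month), annual OOP (and its outpatient/inpatient parts) is divided by 12,
#' and each result is divided by the CPI factor of the household's interview
#' month. The identity CPI (the default) leaves nominal values.
#'
#' @param raw A `raw_survey` (from [generate_survey()] or
#'   [read_survey_csv()]) or a household data frame with columns
#'   `food_weekly`, `oop_annual`, `oop_outpatient_annual`,
#'   `oop_inpatient_annual` (and `month` if a CPI map is used).
#' @param cpi `NULL` (identity), a single deflation factor, or a vector of
#'   factors named by interview month (`"1"`-`"12"`).
#' @param weekly_to_monthly Conversion factor for weekly amounts. Default
#'   `(365.25 / 7) / 12`.
#' @return The input with monthly columns `food_month`, `oop_month`,
#'   `oop_outpatient_month`, `oop_inpatient_month` added; missing inputs stay
#'   missing (never silently zero).
#' @examples
#' # weekly food of 70 becomes 70 * (365.25/7)/12 = 304.375 per month
#' @export
deflate_to_monthly <- function(raw, cpi = NULL,
                               weekly_to_monthly = (365.25 / 7) / 12) {
  hh <- if (inherits(raw, "raw_survey")) raw$households else raw
  money_cols <- c("food_weekly", "oop_annual", "oop_outpatient_annual",
                  "oop_inpatient_annual", "exp_month")
  for (col in intersect(money_cols, names(hh))) {
    bad <- which(!is.na(hh[[col]]) & hh[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("Negative `%s` for household %s.", col,
                    paste(hh$household_id[bad[seq_len(min(3, length(bad)))]],
                          collapse = ", ")))
    }
  }
  f <- cpi_factor(hh, cpi)
  hh$food_month <- hh$food_weekly * weekly_to_monthly / f
  hh$oop_month <- hh$oop_annual / 12 / f
  hh$oop_outpatient_month <- hh$oop_outpatient_annual / 12 / f
  hh$oop_inpatient_month <- hh$oop_inpatient_annual / 12 / f
  if (inherits(raw, "raw_survey")) {
    raw$households <- hh
    raw
  } else {
    hh
  }
}

cpi_factor <- function(hh, cpi) {
  if (is.null(cpi)) return(1)
  if (length(cpi) == 1 && is.null(names(cpi))) {
    if (cpi <= 0) abort("CPI factor must be positive.")
    return(as.numeric(cpi))
  }
  if (is.null(hh$month)) abort("A month-indexed CPI map requires a `month` column.")
  f <- unname(cpi[as.character(hh$month)])
  if (any(is.na(f))) abort("CPI map has no factor for some interview months.")
  if (any(f <= 0)) abort("CPI factors must be positive.")
  f
}

#' Clean a deflated survey: impute, exclude, and log
#'
#' Applies the deterministic cleaning rules in their fixed order:
#' \enumerate{
#'   \item missing monthly OOP is supplemented by the sum of the outpatient
#'     and inpatient OOP parts when both are present;
#'   \item missing household size is supplemented by the number of member
#'     rows sharing the household's family code;
#'   \item households whose food expenditure is still missing cannot be
#'     supplemented and are deleted;
#'   \item households whose size could not be supplemented (no member rows)
#'     are likewise deleted.
#' }
#' Imputation never changes a non-missing value. Every rule appends a row to
#' the exclusion log (retrievable with [exclusion_log()]), so the sample
#' screening flow is fully reconstructible. Households spending more on food
#' than their total consumption are kept but marked in `food_exceeds_exp`;
#' the capacity-to-pay branch rule handles them downstream.
#'
#' @param raw A deflated `raw_survey`, or a household data frame plus
#'   `members`.
#' @param members Member-level table (required when `raw` is a data frame).
#' @return A tibble of cleaned household records (`hhsize` final, monthly
#'   monetary fields, `size_class`, `food_exceeds_exp`, all covariates), with
#'   the exclusion log attached as attribute `"exclusions"`.
#' @export
clean_records <- function(raw, members = NULL) {
  if (inherits(raw, "raw_survey")) {
    hh <- raw$households
    members <- raw$members
  } else {
    hh <- raw
  }
  if (is.null(hh$food_month)) {
    abort("No `food_month` column: call `deflate_to_monthly()` before `clean_records()`.")
  }
  n0 <- nrow(hh)
  log <- tibble(rule = character(), affected = integer(),
                removed = integer(), remaining = integer())
  note <- function(rule, affected, removed, remaining) {
    dplyr::bind_rows(log, tibble(rule = rule, affected = as.integer(affected),
                                 removed = as.integer(removed),
                                 remaining = as.integer(remaining)))
  }

  # 1. OOP <- outpatient + inpatient parts
  can <- is.na(hh$oop_month) & !is.na(hh$oop_outpatient_month) &
    !is.na(hh$oop_inpatient_month)
  hh$oop_month[can] <- hh$oop_outpatient_month[can] + hh$oop_inpatient_month[can]
  log <- note("impute_oop_from_parts", sum(can), 0, n0)

  # 2. household size <- member-row count under the same family code
  counts <- dplyr::count(members, .data$household_id, name = "n_members")
  need <- is.na(hh$hhsize)
  idx <- match(hh$household_id, counts$household_id)
  filled <- need & !is.na(idx)
  hh$hhsize[filled] <- counts$n_members[idx[filled]]
  log <- note("impute_hhsize_from_members", sum(filled), 0, n0)

  # 3. delete households whose food expenditure cannot be supplemented
  drop_food <- is.na(hh$food_month)
  hh <- hh[!drop_food, , drop = FALSE]
  log <- note("drop_missing_food", sum(drop_food), sum(drop_food), nrow(hh))

  # 4. delete households whose size has no imputation path
  drop_size <- is.na(hh$hhsize)
  hh <- hh[!drop_size, , drop = FALSE]
  log <- note("drop_unresolved_hhsize", sum(drop_size), sum(drop_size), nrow(hh))

  hh$size_class <- size_class_of(hh$hhsize)
  hh$food_exceeds_exp <- !is.na(hh$exp_month) & hh$food_month > hh$exp_month
  n_flag <- sum(hh$food_exceeds_exp)
  log <- note("flag_food_exceeds_exp", n_flag, 0, nrow(hh))

  out <- as_tibble(hh)
  attr(out, "exclusions") <- log
  out
}

#' Retrieve the exclusion log of a cleaned survey
#'
#' @param x The tibble returned by [clean_records()].
#' @return A tibble with one row per cleaning rule: `rule`, `affected`
#'   (households imputed or flagged), `removed`, `remaining`.
#' @export
exclusion_log <- function(x) {
  log <- attr(x, "exclusions")
  if (is.null(log)) abort("`x` carries no exclusion log; was it produced by `clean_records()`?")
  log
}

#' Flag chronic-disease households from member-level answers
#'
#' A household is a chronic-disease household if any member answers yes to at
#' least one of the 14 chronic-disease screening questions. Household-level
#' indicators for the five focal conditions (heart disease, stroke, malignant
#' tumour, chronic lung disease, diabetes) and the disease-count class (one
#' condition vs more than one) are taken from the householder's answers.
#'
#' @param members Member table with `household_id`, `is_householder`, and one
#'   logical column per screening question (see
#'   [default_disease_prevalences()] for the 14 names).
#' @return A tibble with one row per household: `chronic_household`, the five
#'   focal indicators (`"Yes"`/`"No"`), and `disease_count_class`
#'   (`"none"`, `"1_type"`, `"multi_type"`).
#' @export
flag_chronic_household <- function(members) {
  dis <- names(default_disease_prevalences())
  miss <- setdiff(dis, names(members))
  if (length(miss)) {
    abort(paste0("Member table is missing chronic-disease columns: ",
                 paste(miss, collapse = ", ")))
  }
  ans <- as.matrix(members[, dis])
  if (any(is.na(ans))) {
    abort("Every member must answer all 14 chronic-disease questions (NA found).")
  }
  members$any_disease <- rowSums(ans) > 0
  members$n_conditions <- rowSums(ans)

  hh_any <- members |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(chronic_household = any(.data$any_disease), .groups = "drop")

  heads <- dplyr::filter(members, .data$is_householder)
  if (!all(hh_any$household_id %in% heads$household_id)) {
    abort("Some households have no householder row in the member table.")
  }
  focal <- c("heart_disease", "stroke", "malignant_tumour",
             "chronic_lung_disease", "diabetes")
  head_tbl <- tibble(household_id = heads$household_id)
  for (d in focal) head_tbl[[d]] <- ifelse(heads[[d]], "Yes", "No")
  head_tbl$disease_count_class <- factor(
    dplyr::case_when(heads$n_conditions == 0 ~ "none",
                     heads$n_conditions == 1 ~ "1_type",
                     TRUE ~ "multi_type"),
    levels = c("none", "1_type", "multi_type")
  )
  dplyr::left_join(hh_any, head_tbl, by = "household_id")
}

#' Assign per-capita expenditure quintiles
#'
#' Ranks households by per-capita consumption expenditure
#' (`exp_month / hhsize`) in ascending order and splits them into five
#' (near-)equal groups: level 1 is the poorest fifth, level 5 the wealthiest.
#' When the sample size is not a multiple of five, the lower groups receive
#' the extra households (sizes differ by at most one). Ties in per-capita
#' expenditure are broken by `household_id` order, so the assignment does not
#' depend on input row order.
#'
#' @param data Household data frame with `exp_month`, `hhsize`,
#'   `household_id`.
#' @return `data` with an `econ_level` factor (`"1"`-`"5"`) added.
#' @export
assign_economic_quintile <- function(data) {
  n <- nrow(data)
  if (n < 5) abort("Quintile assignment needs at least 5 households.")
  percap <- data$exp_month / data$hhsize
  ord <- order(percap, data$household_id)
  sizes <- n %/% 5 + (1:5 <= n %% 5)
  level <- integer(n)
  level[ord] <- rep(1:5, times = sizes)
  data$econ_level <- factor(level, levels = 1:5)
  data
}
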