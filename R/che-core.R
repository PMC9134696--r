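#' Food share of household consumption
#'
#' The share of food expenditure in total household consumption expenditure,
#' `food / exp`. The value is deliberately not clamped to `[0, 1]`: real
#' surveys contain households whose reported food spending exceeds total
#' consumption, and those are passed through (and flagged downstream) rather
#' than silently altered.
#'
#' @param food Monthly food expenditure (currency units), non-negative.
#' @param exp Monthly household consumption expenditure, strictly positive.
#' @return Numeric vector of food shares.
#' @examples
#' food_share(400, 1000) # 0.4
#' @export
food_share <- function(food, exp) {
  if (any(exp <= 0)) {
    abort("`exp` must be strictly positive: degenerate households (zero consumption) must be excluded upstream.")
  }
  if (any(food < 0)) abort("`food` must be non-negative.")
  food / exp
}

#' Equivalized household size
#'
#' Adjusts household size for economies of scale in consumption using the
#' power equivalence scale `hhsize^beta`. The default exponent `beta = 0.56`
#' is the WHO value estimated from household surveys in 59 countries.
#'
#' @param hhsize Surveyed household size, integer-valued, `>= 1`.
#' @param beta Equivalence-scale exponent, `> 0`. Default `0.56`.
#' @return Equivalized size (dimensionless).
#' @examples
#' equivalized_size(4) # 4^0.56
#' @export
equivalized_size <- function(hhsize, beta = 0.56) {
  if (any(hhsize < 1)) abort("`hhsize` must be >= 1.")
  if (length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    abort("`beta` must be a single positive number.")
  }
  hhsize^beta
}

#' Survey-internal food-based poverty line
#'
#' The subsistence benchmark per equivalent adult: the weighted mean of
#' equivalized food expenditure over households whose food share lies strictly
#' between the lower and upper band percentiles (default the 45th and 55th) of
#' the food-share distribution. Restricting to the middle of the food-share
#' ranking reduces measurement error from extreme households.
#'
#' Percentile values are computed by linear interpolation between order
#' statistics ([stats::quantile()] type 7). The band is open
#' (`food45 < foodexp < food55`); if no household falls strictly inside —
#' possible in tiny or heavily tied surveys — the closed band
#' `[food45, food55]` is used instead.
#'
#' @param data A data frame with one row per household.
#' @param food_share_col,eqfood_col Columns holding the food share and the
#'   equivalized food expenditure.
#' @param band Numeric length-2, percentile bounds in `[0, 100]`,
#'   `lower < upper`. Default `c(45, 55)`.
#' @param weights Optional column of non-negative household weights
#'   (default: all 1).
#' @param rank_by Ranking key for the band. `"food_share"` (the WHO
#'   convention, default) ranks households by food share; `"expenditure"`
#'   selects the band on total consumption expenditure instead (requires an
#'   `exp_month` column).
#' @return The poverty line, a single non-negative number (currency units per
#'   equivalent adult).
#' @export
poverty_line <- function(data, food_share_col = "food_share",
                         eqfood_col = "eqfood", band = c(45, 55),
                         weights = NULL, rank_by = c("food_share", "expenditure")) {
  rank_by <- match.arg(rank_by)
  if (nrow(data) == 0) abort("Cannot compute a poverty line from an empty survey.")
  if (length(band) != 2 || band[1] < 0 || band[2] > 100 || band[1] >= band[2]) {
    abort("`band` must be percentile bounds (lower, upper) with 0 <= lower < upper <= 100.")
  }
  key <- if (rank_by == "food_share") data[[food_share_col]] else data[["exp_month"]]
  if (is.null(key)) abort("Ranking column not found in `data`.")
  eqfood <- data[[eqfood_col]]
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(w < 0)) abort("Household weights must be non-negative.")

  qs <- quantile(key, probs = band / 100, type = 7, names = FALSE)
  inside <- key > qs[1] & key < qs[2]
  if (!any(inside)) inside <- key >= qs[1] & key <= qs[2] # closed-bound fallback
  if (!any(inside) || sum(w[inside]) == 0) {
    abort(sprintf("No household (with positive weight) falls in the %g-%g percentile band.", band[1], band[2]))
  }
  weighted_mean(eqfood[inside], w[inside])
}

#' Household capacity to pay
#'
#' Non-subsistence spending: consumption expenditure minus subsistence
#' expenditure when the household spends at least the subsistence amount on
#' food (`se <= food`), otherwise minus actual food spending (`se >= food`).
#' At equality the two branches coincide. The result may be non-positive for
#' extreme households; such values are passed through (the CHE indicator
#' handles them) rather than raised as errors.
#'
#' @param exp Monthly consumption expenditure.
#' @param food Monthly food expenditure.
#' @param se Monthly subsistence expenditure (`poverty line x eqsize`).
#' @return Capacity to pay, same length as the inputs.
#' @examples
#' capacity_to_pay(1000, 400, 300) # 700: se below food, subtract se
#' capacity_to_pay(1000, 300, 400) # 700: se above food, subtract food
#' @export
capacity_to_pay <- function(exp, food, se) {
  if (any(exp < 0) || any(food < 0) || any(se < 0)) {
    abort("`exp`, `food` and `se` must be non-negative.")
  }
  ifelse(se <= food, exp - se, exp - food)
}

#' Out-of-pocket burden and catastrophic expenditure flag
#'
#' Computes the out-of-pocket share of capacity to pay, `oop / ctp`, and flags
#' catastrophic health expenditure when that share equals or exceeds the
#' threshold (default 40%; the boundary is inclusive). For households with
#' non-positive capacity to pay the share is undefined (`NA`); any positive
#' out-of-pocket spending then counts as catastrophic — the conservative
#' convention for households already at or below subsistence.
#'
#' @param oop Monthly out-of-pocket health expenditure, non-negative.
#' @param ctp Monthly capacity to pay (may be non-positive).
#' @param threshold CHE cutoff on the burden share, in `(0, 1]`. Default `0.4`.
#' @param degenerate_is_che Should positive OOP with `ctp <= 0` be flagged as
#'   CHE? Default `TRUE`.
#' @return A tibble with columns `oopctp` and `cata` (integer 0/1).
#' @examples
#' che_indicator(400, 1000) # share 0.4, flagged (boundary inclusive)
#' @export
che_indicator <- function(oop, ctp, threshold = 0.4, degenerate_is_che = TRUE) {
  if (any(oop < 0)) abort("`oop` must be non-negative.")
  if (length(threshold) != 1 || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1].")
  }
  pos <- ctp > 0
  oopctp <- ifelse(pos, oop / ctp, NA_real_)
  cata <- integer(length(oop))
  cata[pos] <- as.integer(oopctp[pos] >= threshold)
  if (degenerate_is_che) cata[!pos] <- as.integer(oop[!pos] > 0)
  tibble(oopctp = oopctp, cata = cata)
}

#' Run the full catastrophic health expenditure chain
#'
#' Applies the WHO capacity-to-pay methodology to a cleaned household table:
#' food share, equivalized size `hhsize^beta`, equivalized food expenditure
#' `food / eqsize`, one survey-wide food-based poverty line, subsistence
#' expenditure `pl x eqsize`, capacity to pay, out-of-pocket burden share, and
#' the CHE flag at the threshold.
#'
#' @param data A cleaned household data frame with columns `household_id`,
#'   `hhsize`, `food_month`, `exp_month`, `oop_month` (all monetary fields on
#'   the same monthly, deflated scale).
#' @param beta Equivalence-scale exponent. Default `0.56`.
#' @param band Poverty-line percentile band. Default `c(45, 55)`.
#' @param threshold CHE cutoff on the burden share. Default `0.4`.
#' @param weights Optional name of a weight column; default unit weights
#'   (sampling weights are not applied unless supplied).
#' @param rank_by Ranking key for the poverty-line band; see [poverty_line()].
#' @return A `che_survey` object: list with `results` (one `CHEResult` row per
#'   household: `household_id`, `food_share`, `eqsize`, `eqfood`, `se`, `ctp`,
#'   `oopctp`, `cata`, plus flags for degenerate capacity to pay and food
#'   share above one), the poverty line `pl`, the parameters, and the
#'   (weighted) CHE incidence in percent.
#' @examples
#' hh <- tibble::tibble(household_id = "h1", hhsize = 1,
#'                      food_month = 400, exp_month = 1000, oop_month = 300)
#' run_che(hh)
#' @export
run_che <- function(data, beta = 0.56, band = c(45, 55), threshold = 0.4,
                    weights = NULL, rank_by = c("food_share", "expenditure")) {
  rank_by <- match.arg(rank_by)
  need <- c("household_id", "hhsize", "food_month", "exp_month", "oop_month")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("`data` is missing columns: ", paste(miss, collapse = ", ")))

  res <- tibble(
    household_id = data$household_id,
    food_share   = food_share(data$food_month, data$exp_month),
    eqsize       = equivalized_size(data$hhsize, beta),
  )
  res$eqfood <- data$food_month / res$eqsize

  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (rank_by == "expenditure") res$exp_month <- data$exp_month
  res$.w <- w
  pl <- poverty_line(res, band = band, weights = ".w", rank_by = rank_by)
  res$.w <- NULL
  if (rank_by == "expenditure") res$exp_month <- NULL

  res$se  <- pl * res$eqsize
  res$ctp <- capacity_to_pay(data$exp_month, data$food_month, res$se)
  ind <- che_indicator(data$oop_month, res$ctp, threshold = threshold)
  res$oopctp <- ind$oopctp
  res$cata   <- ind$cata
  res$ctp_nonpositive <- res$ctp <= 0
  res$food_share_above_one <- res$food_share > 1

  out <- list(
    results = res, pl = pl, beta = beta, band = band, threshold = threshold,
    rank_by = rank_by, n = nrow(res),
    incidence = 100 * sum(w * res$cata) / sum(w)
  )
  class(out) <- "che_survey"
  out
}

#' @export
print.che_survey <- function(x, ...) {
  cat("<che_survey> ", x$n, " households\n", sep = "")
  cat(sprintf("  poverty line: %.4f per equivalent adult (band %g-%g, rank by %s)\n",
              x$pl, x$band[1], x$band[2], x$rank_by))
  cat(sprintf("  beta = %g, threshold = %g\n", x$beta, x$threshold))
  cat(sprintf("  CHE incidence: %.2f%%\n", x$incidence))
  invisible(x)
}

#' Tidy per-household CHE results
#'
#' @param x A `che_survey` object.
#' @param ... Unused.
#' @return The per-household results tibble (one `CHEResult` row each).
#' @method tidy che_survey
#' @export
tidy.che_survey <- function(x, ...) x$results

#' One-row survey-level CHE summary
#'
#' @param x A `che_survey` object.
#' @param ... Unused.
#' @return A one-row tibble: households, poverty line, parameters, CHE count
#'   and incidence (%).
#' @method glance che_survey
#' @export
glance.che_survey <- function(x, ...) {
  tibble(
    n_households = x$n, pl = x$pl, beta = x$beta,
    band_lower = x$band[1], band_upper = x$band[2],
    threshold = x$threshold, n_che = sum(x$results$cata),
    incidence = x$incidence
  )
}

#' Plot the distribution of out-of-pocket burden shares
#'
#' Histogram of `oop / ctp` with the CHE threshold marked; households beyond
#' twice the threshold are collected in the last bin.
#'
#' @param object A `che_survey` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot che_survey
#' @export
autoplot.che_survey <- function(object, ...) {
  df <- dplyr::filter(object$results, !is.na(.data$oopctp))
  df$oopctp_capped <- pmin(df$oopctp, 2 * object$threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$oopctp_capped)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2, colour = "red") +
    ggplot2::labs(
      x = "out-of-pocket share of capacity to pay (capped)",
      y = "households",
      title = sprintf("CHE incidence %.2f%% at threshold %g", object$incidence, object$threshold)
    )
}
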