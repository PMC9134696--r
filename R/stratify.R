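#' Pearson chi-square test of homogeneity on a contingency table
#'
#' Classic Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the table margins and `df = (r - 1)(c - 1)`; the p-value is the upper tail
#' of the chi-square distribution. No continuity correction is applied by
#' default; the Yates correction is available for 2x2 tables behind a flag.
#'
#' @param counts Non-negative r x c matrix of counts, r, c >= 2.
#' @param correct Apply the Yates continuity correction (2x2 only). Default
#'   `FALSE`.
#' @return A list: `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chi_square_test(matrix(c(30, 10, 70, 90), 2)) # 12.5 on 1 df
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("Need at least a 2x2 table.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0)) abort(sprintf("Row %d of the table has zero margin.", which(rs == 0)[1]))
  if (any(cs == 0)) abort(sprintf("Column %d of the table has zero margin.", which(cs == 0)[1]))
  expected <- outer(rs, cs) / sum(counts)
  dev <- abs(counts - expected)
  if (correct) {
    if (!all(dim(counts) == c(2, 2))) abort("Yates correction applies to 2x2 tables only.")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Stratified CHE incidence table
#'
#' Per-stratum sample counts, (weighted) CHE counts and incidence in percent,
#' with a Pearson chi-square comparison of the strata x (CHE, no-CHE)
#' contingency table attached (computed on unweighted counts). Empty strata
#' are dropped with a message.
#'
#' @param data Household data frame containing the CHE flag and the
#'   stratifier (typically cleaned records joined to `tidy(run_che(...))`).
#' @param stratifier Stratifying column (tidy-eval).
#' @param cata Name of the 0/1 CHE column. Default `"cata"`.
#' @param weights Optional name of a weight column; default unit weights.
#' @param scope Free-text label recording what the comparison spans (e.g.
#'   within one disease group, or disease vs no-disease). Stored, not
#'   interpreted.
#' @return An `incidence_table` object: tibble with `stratum`, `n`, `n_che`,
#'   `incidence` (%, 2 dp in printing), and the chi-square comparison as
#'   attributes (`chi_square`, `df`, `p_value`, `scope`).
#' @export
incidence_table <- function(data, stratifier, cata = "cata", weights = NULL,
                            scope = "across strata") {
  strat <- enquo(stratifier)
  val <- tryCatch(rlang::eval_tidy(strat), error = function(e) NULL)
  if (is.character(val) && length(val) == 1) strat <- rlang::new_quosure(rlang::sym(val))
  strat_name <- as_name(strat)
  if (is.null(data[[strat_name]])) abort(sprintf("Stratifier `%s` not found.", strat_name))
  if (any(is.na(data[[strat_name]]))) abort("Every household must have a stratifier category.")
  y <- data[[cata]]
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  data$.y <- y
  data$.w <- w

  tab <- data |>
    dplyr::group_by(stratum = !!strat) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_che = sum(.data$.w * .data$.y),
      incidence = 100 * sum(.data$.w * .data$.y) / sum(.data$.w),
      .groups = "drop"
    )
  if (is.factor(data[[strat_name]])) {
    empty <- setdiff(levels(data[[strat_name]]), as.character(tab$stratum))
    if (length(empty)) {
      message("Dropping empty strata: ", paste(empty, collapse = ", "))
    }
  }

  counts <- cbind(
    che = vapply(split(y, data[[strat_name]], drop = TRUE), sum, numeric(1)),
    no_che = vapply(split(1 - y, data[[strat_name]], drop = TRUE), sum, numeric(1))
  )
  chi <- if (nrow(counts) >= 2 && all(rowSums(counts) > 0) && all(colSums(counts) > 0)) {
    chi_square_test(counts)
  } else {
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }

  structure(tab, class = c("incidence_table", class(tab)),
            stratifier = strat_name, chi_square = chi$statistic,
            df = chi$df, p_value = chi$p_value, scope = scope)
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("CHE incidence by ", attr(x, "stratifier"),
      " (", attr(x, "scope"), ")\n", sep = "")
  y <- as_tibble(x)
  y$incidence <- round(y$incidence, 2)
  print(y)
  if (!is.na(attr(x, "chi_square"))) {
    cat(sprintf("chi-square = %.4f, df = %d, p = %.4g\n",
                attr(x, "chi_square"), attr(x, "df"), attr(x, "p_value")))
  }
  invisible(x)
}

#' One-row summary of an incidence table's group comparison
#'
#' @param x An `incidence_table`.
#' @param ... Unused.
#' @return Tibble with the stratifier, number of strata, total n, and the
#'   chi-square comparison.
#' @method glance incidence_table
#' @export
glance.incidence_table <- function(x, ...) {
  tibble(
    stratifier = attr(x, "stratifier"), n_strata = nrow(x), n = sum(x$n),
    chi_square = attr(x, "chi_square"), df = attr(x, "df"),
    p_value = attr(x, "p_value"), scope = attr(x, "scope")
  )
}

#' Bar chart of stratified CHE incidence
#'
#' @param object An `incidence_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot incidence_table
#' @export
autoplot.incidence_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$incidence)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = attr(object, "stratifier"), y = "CHE incidence (%)")
}

#' Quintile summary of household economics and CHE incidence
#'
#' Mean monthly monetary value (consumption expenditure by default) and CHE
#' incidence per economic quintile, side by side for the full sample and the
#' chronic-disease subsample — the comparison surface used to contrast
#' disease-burdened households with the whole population across wealth
#' groups. Empty quintile-population cells are reported as missing.
#'
#' @param data Household data frame with `econ_level`, `chronic_household`,
#'   the CHE flag, and the monetary column.
#' @param value Name of the monetary column to average. Default
#'   `"exp_month"`.
#' @param cata Name of the 0/1 CHE column. Default `"cata"`.
#' @return A tibble: `econ_level`, `population` (`"all"` /
#'   `"chronic_disease"`), `n`, `mean_value`, `incidence`.
#' @export
quintile_summary <- function(data, value = "exp_month", cata = "cata") {
  if (is.null(data$econ_level)) abort("Assign quintiles first (`assign_economic_quintile()`).")
  if (is.null(data$chronic_household)) abort("`chronic_household` flag not set.")
  one_pop <- function(d, label) {
    d |>
      dplyr::group_by(econ_level = .data$econ_level, .drop = FALSE) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_value = ifelse(dplyr::n() == 0, NA_real_, mean(.data[[value]])),
        incidence = ifelse(dplyr::n() == 0, NA_real_,
                           100 * mean(.data[[cata]])),
        .groups = "drop"
      ) |>
      dplyr::mutate(population = label, .after = "econ_level")
  }
  dplyr::bind_rows(
    one_pop(data, "all"),
    one_pop(dplyr::filter(data, .data$chronic_household), "chronic_disease")
  )
}
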