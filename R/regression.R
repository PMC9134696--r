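#' Design specification for the multivariable CHE model
#'
#' Ordered model terms with their coding and reference levels, as used in
#' multivariable CHE risk models: householder age (numeric); region (ref
#' east); family economic level (ref poorest quintile); household-size class
#' (ref single-person); labour participation (ref no); member aged 65+ (ref
#' no); disabled member (ref no); outpatient use in the past month (ref no);
#' inpatient use in the past year (ref no); the five focal chronic-disease
#' indicators (ref no); and insurance type (ref URRBMI). Categorical terms
#' are dummy-coded with `levels - 1` columns.
#'
#' @param extended Also include the descriptive covariates (householder sex,
#'   marital status, residence, education, self-rated health) that are
#'   tabulated but not part of the default fitted model. Default `FALSE`.
#' @return A tibble with columns `variable`, `column`, `type`, `levels`
#'   (list), `ref`.
#' @export
che_design_spec <- function(extended = FALSE) {
  yn <- c("No", "Yes")
  spec <- tibble(
    variable = c("age", "region", "economic level", "household size class",
                 "labour participation", "member aged 65+", "disabled member",
                 "outpatient past month", "inpatient past year",
                 "heart disease", "stroke", "malignant tumour",
                 "chronic lung disease", "diabetes", "insurance type"),
    column = c("age", "region", "econ_level", "size_class", "labour",
               "member_65plus", "disabled_member", "outpatient_month",
               "inpatient_year", "heart_disease", "stroke",
               "malignant_tumour", "chronic_lung_disease", "diabetes",
               "insurance"),
    type = c("numeric", rep("categorical", 14)),
    levels = list(NULL, c("East", "Central", "West"), as.character(1:5),
                  c("1", "2", "3plus"), yn, yn, yn, yn, yn,
                  yn, yn, yn, yn, yn,
                  c("URRBMI", "UEBMI", "NRCMS", "URBMI", "Other")),
    ref = c(NA, "East", "1", "1", "No", "No", "No", "No", "No",
            "No", "No", "No", "No", "No", "URRBMI")
  )
  if (extended) {
    extra <- tibble(
      variable = c("sex", "marital status", "residence", "education",
                   "self-rated health"),
      column = c("sex", "marital", "residence", "education", "srh"),
      type = "categorical",
      levels = list(c("Female", "Male"), c("Single", "Married"),
                    c("Rural", "Urban"),
                    c("Illiterate", "Primary", "JuniorOrAbove"),
                    c("Good", "Bad")),
      ref = c("Female", "Single", "Rural", "Illiterate", "Good")
    )
    spec <- dplyr::bind_rows(spec, extra)
  }
  spec
}

# All dummy-column names a spec can produce (used to validate true_beta).
design_dummy_names <- function(spec) {
  unlist(lapply(seq_len(nrow(spec)), function(i) {
    if (spec$type[i] == "numeric") return(spec$column[i])
    lv <- spec$levels[[i]]
    paste0(spec$column[i], setdiff(lv, spec$ref[i]))
  }))
}

# Design matrix (with intercept) for a data frame under a spec; errors name
# the household and term when an unseen category appears.
design_matrix_for <- function(data, spec) {
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  term_of <- c(`(Intercept)` = "(Intercept)")
  for (i in seq_len(nrow(spec))) {
    col <- spec$column[i]
    if (is.null(data[[col]])) abort(sprintf("Design term `%s` not found in the data.", col))
    v <- data[[col]]
    if (spec$type[i] == "numeric") {
      if (!is.numeric(v)) abort(sprintf("Design term `%s` must be numeric.", col))
      cols[[col]] <- as.numeric(v)
      term_of[col] <- col
    } else {
      lv <- spec$levels[[i]]
      vv <- as.character(v)
      bad <- which(!vv %in% lv)
      if (length(bad)) {
        abort(sprintf("Household %s has unseen category '%s' for term `%s`.",
                      as.character(data$household_id[bad[1]] %||% bad[1]),
                      vv[bad[1]], col))
      }
      for (l in setdiff(lv, spec$ref[i])) {
        nm <- paste0(col, l)
        cols[[nm]] <- as.numeric(vv == l)
        term_of[nm] <- col
      }
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "term_of") <- term_of
  X
}

#' Build the outcome vector and design matrix for the CHE model
#'
#' Dummy-codes the household covariates against the reference levels of a
#' [che_design_spec()], with the intercept first and columns in spec order,
#' and extracts the 0/1 CHE outcome.
#'
#' @param data Household data frame holding the outcome and every spec term
#'   (typically cleaned records joined to `tidy(run_che(...))`).
#' @param spec A design specification tibble. Default [che_design_spec()].
#' @param outcome Name of the 0/1 outcome column. Default `"cata"`.
#' @return A list with `y` (integer vector) and `X` (numeric matrix with a
#'   `"term_of"` attribute mapping columns to model terms).
#' @export
build_design_matrix <- function(data, spec = che_design_spec(), outcome = "cata") {
  if (is.null(data[[outcome]])) abort(sprintf("Outcome column `%s` not found.", outcome))
  y <- data[[outcome]]
  if (any(is.na(y)) || !all(y %in% c(0, 1))) abort("Outcome must be 0/1 with no missing values.")
  list(y = as.integer(y), X = design_matrix_for(data, spec))
}

#' Fit a binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `logit(p) = X beta`. Convergence when the
#' largest absolute score component falls below `1e-8` or the relative change
#' in log-likelihood falls below `1e-10`, with a cap of 100 iterations.
#' Standard errors come from the inverse observed information `(X'WX)^{-1}`.
#' Rank-deficient designs and (quasi-)perfect separation are reported as
#' errors rather than silently degraded estimates.
#'
#' @param y Integer 0/1 outcome vector.
#' @param X Numeric design matrix including the intercept column.
#' @param max_iter,tol_score,tol_ll Convergence controls.
#' @return A `che_logit` object: coefficients, standard errors, fitted
#'   probabilities, log-likelihood, convergence info, and the variance matrix.
#' @export
fit_logistic <- function(y, X, max_iter = 100, tol_score = 1e-8, tol_ll = 1e-10) {
  n <- length(y)
  if (nrow(X) != n) abort("`y` and `X` have incompatible sizes.")
  if (n <= ncol(X)) abort("Need more observations than design columns.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(dep, collapse = ", ")))
  }

  beta <- numeric(ncol(X))
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- p * (1 - p)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12) # numerical guard near 0/1
    z <- eta + (y - p) / w
    fit <- lm.fit(X * sqrt(w), z * sqrt(w))
    beta_new <- fit$coefficients
    eta <- drop(X %*% beta_new)
    p <- plogis(eta)
    ll_new <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    score <- drop(crossprod(X, y - p))
    beta <- beta_new
    if (max(abs(score)) < tol_score ||
        abs(ll_new - ll) < tol_ll * (abs(ll) + 1e-10)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (max(abs(beta)) > 30 && (min(p) < 1e-8 || max(p) > 1 - 1e-8)) {
    abort("Perfect or quasi-perfect separation detected: a coefficient diverges and fitted probabilities are pinned at 0/1.")
  }
  if (!converged) warn(sprintf("IRLS did not converge in %d iterations.", max_iter))

  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)

  structure(list(
    coefficients = beta, se = se, vcov = vcov, fitted = p,
    linear_predictor = eta, y = y, X = X,
    log_likelihood = ll, n = n, n_iter = iter, converged = converged,
    term_of = attr(X, "term_of")
  ), class = "che_logit")
}

#' @export
print.che_logit <- function(x, ...) {
  cat("<che_logit> n =", x$n, "| logLik =", round(x$log_likelihood, 2),
      "|", x$n_iter, "IRLS iterations\n")
  print(round(cbind(beta = x$coefficients, se = x$se,
                    OR = exp(x$coefficients)), 4))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(beta)` with the Wald interval
#' `exp(beta +/- z * se)` and a two-sided Wald p-value per term.
#'
#' @param fit A `che_logit` fit.
#' @param conf_level Confidence level. Default `0.95`.
#' @return A tibble: `term`, `estimate` (log-odds), `std_error`, `or`,
#'   `conf_low`, `conf_high`, `statistic` (z), `p_value`.
#' @export
odds_ratios <- function(fit, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients
  se <- fit$se
  tibble(
    term = names(b), estimate = unname(b), std_error = unname(se),
    or = exp(unname(b)),
    conf_low = exp(unname(b) - z * unname(se)),
    conf_high = exp(unname(b) + z * unname(se)),
    statistic = unname(b / se),
    p_value = 2 * pnorm(-abs(unname(b / se)))
  )
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Splits households into `groups` near-equal groups by sorted fitted
#' probability (households with identical fitted probability never straddle a
#' boundary, so group sizes deviate from `n/groups` as needed under heavy
#' ties) and compares observed with expected outcome counts in both outcome
#' classes: `sum over groups of (O1-E1)^2/E1 + (O0-E0)^2/E0`, referred to a
#' chi-square distribution with `groups - 2` degrees of freedom. The default
#' 10 groups gives the conventional 8 degrees of freedom.
#'
#' @param y 0/1 outcomes.
#' @param p Fitted probabilities.
#' @param groups Number of groups, `>= 3`. Default 10.
#' @return A list: `statistic`, `df`, `p_value`, and the per-group table.
#' @export
hosmer_lemeshow <- function(y, p, groups = 10) {
  n <- length(y)
  if (groups < 3) abort("`groups` must be at least 3.")
  if (n < groups) abort("Need at least as many observations as groups.")
  ord <- order(p)
  ys <- y[ord]
  ps <- p[ord]
  # near-equal group boundaries, advanced so that tied probabilities stay together
  target <- round(seq_len(groups) * n / groups)
  bounds <- integer(groups)
  for (g in seq_len(groups)) {
    b <- target[g]
    while (b < n && ps[b + 1] == ps[b]) b <- b + 1
    bounds[g] <- b
  }
  bounds[groups] <- n
  bounds <- unique(cummax(bounds))
  starts <- c(1, head(bounds, -1) + 1)
  grp <- tibble(
    group = seq_along(bounds),
    n = bounds - starts + 1,
    observed_1 = vapply(seq_along(bounds), function(g) sum(ys[starts[g]:bounds[g]]), numeric(1)),
    expected_1 = vapply(seq_along(bounds), function(g) sum(ps[starts[g]:bounds[g]]), numeric(1))
  )
  grp$observed_0 <- grp$n - grp$observed_1
  grp$expected_0 <- grp$n - grp$expected_1
  if (any(grp$expected_1 < 1e-12) || any(grp$expected_0 < 1e-12)) {
    abort("A group has expected count 0 in one outcome class; use fewer groups.")
  }
  stat <- sum((grp$observed_1 - grp$expected_1)^2 / grp$expected_1 +
                (grp$observed_0 - grp$expected_0)^2 / grp$expected_0)
  df <- length(bounds) - 2
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), groups = grp)
}

#' Variance inflation factors of a design matrix
#'
#' For each non-intercept column, regresses it on all other non-intercept
#' columns (ordinary least squares, intercept included) and reports
#' `VIF = 1 / (1 - R^2)`. Exact linear dependence yields an infinite VIF
#' rather than an error. Because categorical terms contribute several dummy
#' columns, a per-term summary aggregates dummies by their maximum VIF.
#'
#' @param X Design matrix with an intercept column named `"(Intercept)"`.
#' @return A tibble: `column`, `term`, `vif`, and attribute `"by_term"` with
#'   the per-term maxima.
#' @export
vif_design <- function(X) {
  keep <- setdiff(colnames(X), "(Intercept)")
  if (length(keep) < 2) abort("VIF needs at least two non-intercept columns.")
  term_of <- attr(X, "term_of")
  vifs <- vapply(keep, function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, setdiff(keep, j), drop = FALSE])
    fit <- lm.fit(Z, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf) # constant column
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- tibble(
    column = keep,
    term = if (is.null(term_of)) keep else unname(term_of[keep]),
    vif = unname(vifs)
  )
  attr(out, "by_term") <- out |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(vif = max(.data$vif), .groups = "drop")
  out
}

#' Fit the multivariable CHE model on a household table
#'
#' Convenience wrapper: builds the design matrix under `spec`, fits the
#' logistic model by IRLS, and attaches odds ratios, the Hosmer-Lemeshow
#' test and VIFs.
#'
#' @param data Household data frame containing the outcome and all spec
#'   terms.
#' @param spec Design specification. Default [che_design_spec()].
#' @param outcome Outcome column name. Default `"cata"`.
#' @param hl_groups Hosmer-Lemeshow groups. Default 10.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return A `che_logit` fit with components `or_table`, `hl`, `vif` added.
#' @export
fit_che_model <- function(data, spec = che_design_spec(), outcome = "cata",
                          hl_groups = 10, conf_level = 0.95) {
  d <- build_design_matrix(data, spec, outcome = outcome)
  fit <- fit_logistic(d$y, d$X)
  fit$or_table <- odds_ratios(fit, conf_level)
  fit$hl <- hosmer_lemeshow(d$y, fit$fitted, groups = hl_groups)
  fit$vif <- vif_design(d$X)
  fit$spec <- spec
  fit
}

#' Tidy coefficients of a CHE logistic fit
#'
#' @param x A `che_logit` object.
#' @param ... Unused.
#' @return One row per design column: log-odds estimate, standard error,
#'   Wald z and p, odds ratio with its confidence interval.
#' @method tidy che_logit
#' @export
tidy.che_logit <- function(x, ...) {
  if (!is.null(x$or_table)) x$or_table else odds_ratios(x)
}

#' One-row fit summary of a CHE logistic fit
#'
#' @param x A `che_logit` object.
#' @param ... Unused.
#' @return Sample size, log-likelihood, convergence info, Hosmer-Lemeshow
#'   statistic/df/p (when computed) and the largest per-term VIF.
#' @method glance che_logit
#' @export
glance.che_logit <- function(x, ...) {
  tibble(
    n = x$n, log_likelihood = x$log_likelihood,
    converged = x$converged, n_iter = x$n_iter,
    hl_statistic = if (is.null(x$hl)) NA_real_ else x$hl$statistic,
    hl_df = if (is.null(x$hl)) NA_integer_ else x$hl$df,
    hl_p = if (is.null(x$hl)) NA_real_ else x$hl$p_value,
    max_vif = if (is.null(x$vif)) NA_real_ else max(x$vif$vif)
  )
}

#' Forest plot of odds ratios
#'
#' @param object A `che_logit` object.
#' @param ... Unused.
#' @return A ggplot object: odds ratios with Wald intervals on a log scale,
#'   intercept omitted.
#' @method autoplot che_logit
#' @export
autoplot.che_logit <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL)
}
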