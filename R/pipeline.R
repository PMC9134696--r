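#' Write a raw survey to CSV files
#'
#' Emits the two-table survey layout: `households.csv` and `members.csv`
#' (column dictionary in [generate_survey()]), plus `truth.csv` and
#' `config.json` when the survey carries generator ground truth.
#'
#' @param raw A `raw_survey`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_survey_csv <- function(raw, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(raw$households, file.path(dir, "households.csv"))
  readr::write_csv(raw$members, file.path(dir, "members.csv"))
  if (!is.null(raw$truth)) readr::write_csv(raw$truth, file.path(dir, "truth.csv"))
  if (!is.null(raw$config)) {
    jsonlite::write_json(unclass(raw$config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a raw survey from CSV files
#'
#' @param household_csv,member_csv Paths to the household- and member-level
#'   tables (layout of [write_survey_csv()]).
#' @return A `raw_survey` object (without generator ground truth).
#' @export
read_survey_csv <- function(household_csv, member_csv) {
  hh <- readr::read_csv(household_csv, show_col_types = FALSE, progress = FALSE)
  mm <- readr::read_csv(member_csv, show_col_types = FALSE, progress = FALSE)
  for (d in names(default_disease_prevalences())) {
    if (!is.null(mm[[d]])) mm[[d]] <- as.logical(mm[[d]])
  }
  structure(list(households = hh, members = mm, truth = NULL, config = NULL),
            class = "raw_survey")
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one input source must
#' be active: either a [synthetic_config()] or the two CSV paths.
#'
#' @param out_dir Output directory for the report bundle.
#' @param synthetic A [synthetic_config()], or `NULL` when reading CSVs.
#' @param household_csv,member_csv Input CSV paths, or `NULL` when
#'   generating synthetically.
#' @param cpi CPI deflation factor(s); see [deflate_to_monthly()].
#' @param beta,band,threshold CHE-chain parameters.
#' @param weights Optional weight column name.
#' @param rank_by Poverty-line ranking key; see [poverty_line()].
#' @param model_population Fit the regression on the chronic-disease
#'   subsample (the study population of CHE risk-factor models) or on all
#'   cleaned households.
#' @param extended_model Include the descriptive covariates in the design
#'   (see [che_design_spec()]).
#' @param hl_groups Hosmer-Lemeshow groups.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, synthetic = NULL, household_csv = NULL,
                            member_csv = NULL, cpi = NULL, beta = 0.56,
                            band = c(45, 55), threshold = 0.4, weights = NULL,
                            rank_by = "food_share",
                            model_population = c("chronic", "all"),
                            extended_model = FALSE, hl_groups = 10) {
  has_csv <- !is.null(household_csv) || !is.null(member_csv)
  if (is.null(synthetic) == !has_csv) {
    abort("Exactly one input source must be set: `synthetic` or the CSV paths.")
  }
  if (has_csv && (is.null(household_csv) || is.null(member_csv))) {
    abort("Both `household_csv` and `member_csv` are required for CSV input.")
  }
  structure(list(
    out_dir = out_dir, synthetic = synthetic, household_csv = household_csv,
    member_csv = member_csv, cpi = cpi, beta = beta, band = band,
    threshold = threshold, weights = weights, rank_by = rank_by,
    model_population = match.arg(model_population),
    extended_model = extended_model, hl_groups = hl_groups
  ), class = "pipeline_config")
}

#' Run the full CHE analysis pipeline and write a report bundle
#'
#' Executes ingest (or synthetic generation), deflation, cleaning with the
#' exclusion log, the capacity-to-pay CHE chain, stratified incidence tables,
#' the quintile summary, and the multivariable logistic model with
#' diagnostics. Writes the bundle to `config$out_dir`:
#' `exclusion_log.csv`, `che_households.csv`, `che_summary.json`,
#' `incidence_<stratifier>.csv` + `incidence_index.json`,
#' `quintile_summary.csv`, `regression_table.csv`, `diagnostics.json`, and
#' `manifest.json` echoing the configuration and the row counts at every
#' stage. Identical configuration (and seed) yields a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`raw`, `clean`,
#'   `che`, `tables`, `fit`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a `pipeline_config`.")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  raw <- if (!is.null(config$synthetic)) {
    generate_survey(config$synthetic)
  } else {
    read_survey_csv(config$household_csv, config$member_csv)
  }
  n_raw <- nrow(raw$households)

  raw <- deflate_to_monthly(raw, cpi = config$cpi)
  clean <- clean_records(raw)
  log <- exclusion_log(clean)
  readr::write_csv(log, file.path(out, "exclusion_log.csv"))

  clean <- dplyr::left_join(clean, flag_chronic_household(raw$members),
                            by = "household_id")
  clean <- assign_economic_quintile(clean)
  clean$age_group <- factor(ifelse(clean$age >= 65, "65plus", "under65"),
                            levels = c("under65", "65plus"))

  che <- run_che(clean, beta = config$beta, band = config$band,
                 threshold = config$threshold, weights = config$weights,
                 rank_by = config$rank_by)
  hh <- dplyr::left_join(clean, tidy(che), by = "household_id")
  readr::write_csv(tidy(che), file.path(out, "che_households.csv"))
  jsonlite::write_json(as.list(glance(che)), file.path(out, "che_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  chronic <- dplyr::filter(hh, .data$chronic_household)
  strats <- c("sex", "age_group", "residence", "education", "marital",
              "size_class", "region", "insurance", "econ_level", "srh",
              "labour", "member_65plus", "disabled_member",
              "outpatient_month", "inpatient_year", "disease_count_class")
  tables <- list()
  for (s in strats) {
    tab <- incidence_table(chronic, s, weights = config$weights,
                           scope = "within chronic-disease households")
    tables[[s]] <- tab
    readr::write_csv(as_tibble(tab), file.path(out, paste0("incidence_", s, ".csv")))
  }
  tab_cmp <- incidence_table(hh, "chronic_household",
                             weights = config$weights,
                             scope = "chronic-disease vs no-disease households")
  tables[["chronic_household"]] <- tab_cmp
  readr::write_csv(as_tibble(tab_cmp), file.path(out, "incidence_chronic_household.csv"))
  idx <- dplyr::bind_rows(lapply(tables, glance))
  jsonlite::write_json(idx, file.path(out, "incidence_index.json"), digits = NA)

  qs <- quintile_summary(hh)
  readr::write_csv(qs, file.path(out, "quintile_summary.csv"))

  model_data <- if (config$model_population == "chronic") chronic else hh
  spec <- che_design_spec(extended = config$extended_model)
  n_cols <- length(design_dummy_names(spec)) + 1
  feasible <- length(unique(model_data$cata)) == 2 && nrow(model_data) > n_cols
  if (feasible) {
    fit <- fit_che_model(model_data, spec = spec, hl_groups = config$hl_groups)
    reg <- dplyr::left_join(tidy(fit),
                            tibble(term = names(fit$term_of),
                                   variable = unname(fit$term_of)),
                            by = "term")
    readr::write_csv(reg, file.path(out, "regression_table.csv"))
    by_term <- attr(fit$vif, "by_term")
    diagnostics <- list(
      hosmer_lemeshow = list(statistic = fit$hl$statistic, df = fit$hl$df,
                             p_value = fit$hl$p_value),
      vif = setNames(as.list(by_term$vif), by_term$term),
      converged = fit$converged, n_iter = fit$n_iter,
      log_likelihood = fit$log_likelihood, n = fit$n
    )
  } else {
    fit <- NULL
    readr::write_csv(tibble(term = character()), file.path(out, "regression_table.csv"))
    diagnostics <- list(
      skipped = TRUE,
      reason = "regression infeasible: outcome has one class or fewer households than design columns",
      n = nrow(model_data)
    )
  }
  jsonlite::write_json(diagnostics, file.path(out, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "chequity",
    version = as.character(utils::packageVersion("chequity")),
    source = if (is.null(config$synthetic)) "csv" else "synthetic",
    seed = if (is.null(config$synthetic)) NA else config$synthetic$seed,
    parameters = list(beta = config$beta, band = config$band,
                      threshold = config$threshold, rank_by = config$rank_by,
                      model_population = config$model_population,
                      extended_model = config$extended_model,
                      hl_groups = config$hl_groups),
    counts = list(raw = n_raw,
                  cleaned = nrow(clean),
                  excluded = sum(log$removed),
                  chronic = nrow(chronic),
                  model = if (is.null(fit)) 0 else fit$n)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(raw = raw, clean = clean, che = che, tables = tables,
                 quintiles = qs, fit = fit, manifest = manifest))
}
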