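# End-to-end orchestration: simulate -> score -> fit -> project, plus the
# descriptive table.

#' Descriptive statistics table
#'
#' Mean and sample SD (n-1 denominator) for every variable of the
#' analysis, in the report order of the study's descriptive table:
#' indices first, then family composition and income, then decision-maker,
#' household and village controls (including the log transforms actually
#' used in the regressions).
#'
#' @param covariates Covariates tibble.
#' @param scores Optional score tibble from [score_dataset()]; adds the
#'   three index rows at the top.
#' @return Tibble with columns `variable`, `mean`, `sd`.
#' @export
describe_survey <- function(covariates, scores = NULL) {
  rf <- regressor_frame(covariates)
  order <- c("ratio_under18", "ratio_18_65", "ratio_over65", "income",
             "gender_dm", "married_dm", "education_dm", "dki",
             "pension", "ln_pension", "off_farm", "distance_km",
             "ln_distance", "land_ha", "ln_land", "crop_diversity",
             "household_size", "property", "village_population",
             "village_distance", "food_market_density", "village_income",
             "ln_village_income", "village_land", "ln_village_land")
  if (!nrow(rf)) stop("empty dataset.", call. = FALSE)
  tab <- tibble::tibble(
    variable = order,
    mean = unname(vapply(order, function(v) mean(rf[[v]]), numeric(1))),
    sd = unname(vapply(order, function(v) sd(rf[[v]]), numeric(1)))
  )
  if (!is.null(scores)) {
    idx <- tibble::tibble(
      variable = c("EI", "CFPS", "CHEI"),
      mean = unname(vapply(c("EI", "CFPS", "CHEI"),
                           function(v) mean(scores[[v]]), numeric(1))),
      sd = unname(vapply(c("EI", "CFPS", "CHEI"),
                         function(v) sd(scores[[v]]), numeric(1)))
    )
    tab <- dplyr::bind_rows(idx, tab)
  }
  tab
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic survey, scores it, produces the descriptive
#' table, fits the main model for each index, optionally runs the default
#' heterogeneity splits and the eight-category SUR, and projects the
#' indices over the income-growth scenario grid using the freshly fitted
#' coefficients. Identical configuration and seed give an identical
#' bundle; with `out_dir` set, every intermediate table is persisted as
#' CSV so each reported cell can be recomputed.
#'
#' @inheritParams generate_survey
#' @param mapping,bounds Pagoda mapping and bounds for scoring.
#' @param indices Outcomes to fit (default all three).
#' @param splits Named list of heterogeneity splits, each a list with
#'   `cut` and optional `thresholds` — e.g.
#'   `list(income = list(cut = "tercile"))`; `NULL` to skip.
#' @param run_sur Fit the SUR system on the eight category intakes?
#' @param scenarios A base [scenario()], or `NULL` to skip projection.
#' @param n_values Income growth rates for the scenario grid.
#' @param on_collinear Collinearity handling passed to the fit stages;
#'   the pipeline default is `"drop"` (small strata can zero out rare
#'   binary controls).
#' @param out_dir Optional directory for CSV outputs.
#' @param quiet Suppress stage messages?
#' @return Object of class `report_bundle`: `descriptives`,
#'   `main_models` (one `diet_fit` per index), `heterogeneity`, `sur`,
#'   `projections`, `scores`, `survey`, and run `meta`.
#' @export
run_pipeline <- function(design = survey_design(),
                         effects = default_effects(),
                         calibration = default_calibration(),
                         mapping = default_pagoda_mapping(),
                         bounds = default_pagoda_bounds(),
                         components = default_chei_components(),
                         indices = c("EI", "CFPS", "CHEI"),
                         splits = list(income = list(cut = "tercile"),
                                       labor_number = list(
                                         cut = "custom", thresholds = 2)),
                         run_sur = TRUE,
                         scenarios = scenario(),
                         n_values = c(0, 0.025, 0.05, 0.075),
                         seed = design$seed,
                         on_collinear = "drop",
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] generating survey (seed %d)", seed)
  survey <- with_stage("simulate",
                       generate_survey(design, effects, calibration,
                                       components, seed = seed))

  say("[score] computing indices for %d households",
      nrow(survey$covariates))
  scores <- with_stage("score",
                       score_dataset(survey$consumption, survey$meals,
                                     mapping, bounds, components))

  descr <- with_stage("describe",
                      describe_survey(survey$covariates, scores))

  dat <- with_stage("fit", analysis_frame(scores, survey$covariates))
  main <- lapply(indices, function(ix) {
    say("[fit] main model for %s", ix)
    with_stage("fit", fit_main_model(dat, regression_spec(ix),
                                     on_collinear = on_collinear))
  })
  names(main) <- indices

  hetero <- NULL
  if (!is.null(splits)) {
    hetero <- lapply(names(splits), function(sv) {
      say("[fit] heterogeneity split on %s", sv)
      s <- splits[[sv]]
      lapply(indices, function(ix) {
        with_stage("fit",
                   run_heterogeneity(dat, regression_spec(ix), sv,
                                     cut = s$cut,
                                     thresholds = s$thresholds,
                                     on_collinear = on_collinear))
      }) |> setNames(indices)
    })
    names(hetero) <- names(splits)
  }

  sur <- NULL
  if (run_sur) {
    say("[fit] SUR over the eight Pagoda categories")
    intakes <- with_stage("fit",
                          standardize_intake(survey$consumption,
                                             survey$meals))
    cat_int <- category_intakes(intakes, mapping)
    sur_dat <- dplyr::inner_join(cat_int, regressor_frame(survey$covariates),
                                 by = "household_id")
    sur <- with_stage("fit",
                      fit_sur(sur_dat, pagoda_categories(),
                              c("ratio_under18", "ratio_over65", "income",
                                default_controls()),
                              fe = "county_id",
                              joint = c("ratio_over65", "income")))
  }

  projections <- NULL
  if (!is.null(scenarios)) {
    say("[project] scenario grid to %d", scenarios$end_year)
    projections <- dplyr::bind_rows(lapply(indices, function(ix) {
      dplyr::mutate(
        scenario_grid(projection_coefs(main[[ix]]), scenarios, n_values),
        index = ix)
    }))
  }

  bundle <- structure(list(
    descriptives = descr, main_models = main, heterogeneity = hetero,
    sur = sur, projections = projections, scores = scores,
    survey = survey,
    meta = list(seed = seed, n_households = nrow(survey$covariates),
                n_scored = nrow(scores),
                package_version =
                  as.character(utils::packageVersion("ruraldiet")),
                timestamp = format(t0, "%Y-%m-%d %H:%M:%S"))),
    class = "report_bundle")

  if (!is.null(out_dir)) {
    say("[write] persisting outputs to %s", out_dir)
    with_stage("write", write_bundle(bundle, out_dir))
  }
  bundle
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_survey(bundle$survey, out_dir)
  readr::write_csv(bundle$scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(bundle$descriptives,
                   file.path(out_dir, "descriptives.csv"))
  main_tab <- dplyr::bind_rows(lapply(names(bundle$main_models), function(ix) {
    dplyr::mutate(coef_table(bundle$main_models[[ix]]), model = ix,
                  stratum = "all")
  }))
  if (!is.null(bundle$heterogeneity)) {
    het_tab <- dplyr::bind_rows(lapply(
      names(bundle$heterogeneity), function(sv) {
        dplyr::bind_rows(lapply(names(bundle$heterogeneity[[sv]]),
                                function(ix) {
          dplyr::mutate(bundle$heterogeneity[[sv]][[ix]]$table,
                        model = ix, split = sv)
        }))
      }))
    readr::write_csv(het_tab, file.path(out_dir, "heterogeneity.csv"))
  }
  readr::write_csv(main_tab, file.path(out_dir, "main_models.csv"))
  if (!is.null(bundle$sur)) {
    readr::write_csv(bundle$sur$wald, file.path(out_dir, "sur_wald.csv"))
  }
  if (!is.null(bundle$projections)) {
    readr::write_csv(bundle$projections,
                     file.path(out_dir, "projection.csv"))
  }
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Dietary-health analysis bundle\n")
  cat(sprintf("  seed %d | %d households generated, %d scored | v%s | %s\n",
              x$meta$seed, x$meta$n_households, x$meta$n_scored,
              x$meta$package_version, x$meta$timestamp))
  cat("  index means:",
      paste(sprintf("%s=%.2f", c("EI", "CFPS", "CHEI"),
                    vapply(c("EI", "CFPS", "CHEI"),
                           function(v) mean(x$scores[[v]]), numeric(1))),
            collapse = "  "), "\n")
  for (ix in names(x$main_models)) {
    tb <- coef_table(x$main_models[[ix]])
    foc <- tb[tb$term %in% c("ratio_under18", "ratio_over65", "income"), ]
    cat(sprintf("  [%s] %s\n", ix,
                paste(sprintf("%s=%.4g%s", foc$term, foc$estimate,
                              foc$stars), collapse = "  ")))
  }
  if (!is.null(x$sur)) {
    cat("  SUR joint Wald:",
        paste(sprintf("%s chi2(%d)=%.2f%s", x$sur$wald$term,
                      x$sur$wald$df, x$sur$wald$wald, x$sur$wald$stars),
              collapse = "  "), "\n")
  }
  if (!is.null(x$projections)) {
    cat(sprintf("  projections: %d series over %d scenarios\n",
                length(unique(paste(x$projections$index,
                                    x$projections$scenario))),
                length(unique(x$projections$scenario))))
  }
  invisible(x)
}
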