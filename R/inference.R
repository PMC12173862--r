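# Regression designs: cluster-robust OLS with county fixed effects,
# subgroup (heterogeneity) drivers, seemingly unrelated regressions with
# joint Wald tests, and LASSO variable selection.

#' Add derived regressors to a covariates table
#'
#' Adds the log transforms used in the regression designs and the derived
#' labor count. Variables with legitimate zeros (pension, market distance,
#' land) use `log(1 + x)`; strictly positive village aggregates use plain
#' `log`. `labor_number` is the implied count of working-age members,
#' `round(household_size * ratio_18_65 / 100)`.
#'
#' @param covariates Covariates tibble as generated by
#'   [generate_survey()] (or read from `covariates.csv`).
#' @return The tibble with columns `ln_pension`, `ln_distance`,
#'   `ln_land`, `ln_village_income`, `ln_village_land`, `labor_number`
#'   appended.
#' @export
regressor_frame <- function(covariates) {
  dplyr::mutate(
    tibble::as_tibble(covariates),
    ln_pension = log1p(.data$pension),
    ln_distance = log1p(.data$distance_km),
    ln_land = log1p(.data$land_ha),
    ln_village_income = log(.data$village_income),
    ln_village_land = log(.data$village_land),
    labor_number = round(.data$household_size * .data$ratio_18_65 / 100)
  )
}

#' Join index scores onto the regression covariates
#'
#' @param scores Score tibble from [score_dataset()].
#' @param covariates Covariates tibble.
#' @return One row per scored household with all regressors attached.
#' @export
analysis_frame <- function(scores, covariates) {
  dplyr::inner_join(tibble::as_tibble(scores),
                    regressor_frame(covariates), by = "household_id")
}

#' Default control set of the main regression design
#'
#' Food-decision-maker, household and village controls, in report order.
#'
#' @return Character vector of regressor-frame column names.
#' @export
default_controls <- function() {
  c("gender_dm", "married_dm", "education_dm", "dki", "ln_pension",
    "off_farm", "ln_distance", "ln_land", "crop_diversity",
    "household_size", "property", "village_population",
    "village_distance", "food_market_density", "ln_village_income",
    "ln_village_land")
}

#' Regression specification for the main model
#'
#' The outcome is regressed on the family-composition shares (the 18-65
#' share is the omitted reference category), per-capita income, the
#' control set, and county fixed effects; standard errors are adjusted
#' for clustering on `cluster`. With one observation per household,
#' household-level clustering is operationally identical to
#' heteroskedasticity-robust (HC1) standard errors; village or county
#' clustering is available through the same argument.
#'
#' @param outcome Outcome column name (`"EI"`, `"CFPS"`, `"CHEI"`, or a
#'   food-category intake column).
#' @param focal Focal regressors.
#' @param controls Control regressors; see [default_controls()].
#' @param fe Fixed-effect factor column (default `"county_id"`); `NULL`
#'   for none.
#' @param cluster Cluster factor column (default `"household_id"`).
#' @return Object of class `regression_spec`.
#' @export
regression_spec <- function(outcome,
                            focal = c("ratio_under18", "ratio_over65",
                                      "income"),
                            controls = default_controls(),
                            fe = "county_id",
                            cluster = "household_id") {
  dup <- intersect(focal, controls)
  if (length(dup)) {
    stop("regressor(s) listed as both focal and control: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if ("ratio_18_65" %in% c(focal, controls)) {
    stop("ratio_18_65 is the omitted reference category and cannot be a ",
         "regressor.", call. = FALSE)
  }
  structure(list(outcome = outcome, focal = focal, controls = controls,
                 fe = fe, cluster = cluster),
            class = "regression_spec")
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "***", p < 0.05 ~ "**", p < 0.1 ~ "*",
                   TRUE ~ "")
}

#' Fit the main model by OLS with cluster-robust standard errors
#'
#' Ordinary least squares of the outcome on the focal regressors, the
#' controls and county fixed-effect dummies; the covariance matrix is the
#' clustered sandwich estimator with the HC1-type small-sample factor
#' (`G/(G-1) * (n-1)/(n-k)`; for singleton clusters this reduces to the
#' plain HC1 heteroskedasticity-robust estimator). Rows with any missing
#' field are dropped listwise and counted. t statistics are referred to a
#' t distribution with `G - 1` degrees of freedom, `G` the number of
#' clusters.
#'
#' @param data Analysis frame from [analysis_frame()] (or any data frame
#'   with the needed columns).
#' @param spec A [regression_spec()].
#' @param on_collinear `"error"` (default) to fail on perfectly collinear
#'   regressors, `"drop"` to drop the aliased terms with a warning.
#' @return Object of class `diet_fit`: coefficient table (`tidy`), the
#'   underlying `lm` fit, the cluster-robust covariance, `n`,
#'   `n_dropped`, and the spec.
#' @export
fit_main_model <- function(data, spec, on_collinear = c("error", "drop")) {
  stopifnot(inherits(spec, "regression_spec"))
  on_collinear <- match.arg(on_collinear)
  vars <- c(spec$outcome, spec$focal, spec$controls, spec$fe, spec$cluster)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, vars, drop = FALSE]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (!nrow(df)) stop("no complete rows to fit on.", call. = FALSE)
  cl <- factor(df[[spec$cluster]])
  if (any(is.na(cl)) || !nlevels(cl)) {
    stop("empty cluster factor.", call. = FALSE)
  }

  rhs <- c(spec$focal, spec$controls)
  if (!is.null(spec$fe)) {
    df[[spec$fe]] <- factor(df[[spec$fe]])
    rhs <- c(rhs, spec$fe)
  }
  # the FE factor leads the formula so that collinear controls (not the
  # absorbed dummies) are the terms lm aliases
  if (!is.null(spec$fe)) rhs <- c(spec$fe, setdiff(rhs, spec$fe))
  fit <- lm(stats::reformulate(rhs, response = spec$outcome), data = df)
  for (pass in 1:5) {
    if (!anyNA(coef(fit))) break
    alias_pos <- which(is.na(coef(fit)))
    labs <- attr(stats::terms(fit), "term.labels")
    alias_terms <- unique(labs[attr(model.matrix(fit), "assign")[alias_pos]])
    if (on_collinear == "error") {
      stop("perfectly collinear regressor(s): ",
           paste(alias_terms, collapse = ", "), call. = FALSE)
    }
    warning("dropping collinear term(s): ",
            paste(alias_terms, collapse = ", "), call. = FALSE)
    rhs <- setdiff(rhs, alias_terms)
    fit <- lm(stats::reformulate(rhs, response = spec$outcome), data = df)
  }
  if (nrow(df) <= length(coef(fit))) {
    stop("fewer rows than parameters.", call. = FALSE)
  }

  vc <- sandwich::vcovCL(fit, cluster = cl, type = "HC1")
  est <- coef(fit)
  se <- sqrt(diag(vc))
  G <- nlevels(droplevels(cl))
  tstat <- est / se
  p <- 2 * pt(abs(tstat), df = G - 1, lower.tail = FALSE)
  is_fe <- if (is.null(spec$fe)) rep(FALSE, length(est)) else {
    startsWith(names(est), spec$fe)
  }
  tidy <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    t = unname(tstat), p = unname(p), stars = significance_stars(p),
    fixed_effect = is_fe
  )
  structure(list(tidy = tidy, model = fit, vcov = vc, n = nrow(df),
                 n_dropped = n_dropped, n_clusters = G, spec = spec),
            class = "diet_fit")
}

#' Coefficient table of a fitted model
#'
#' @param fit A `diet_fit`.
#' @param include_fe Keep the fixed-effect dummy rows? Default `FALSE`.
#' @return Tibble with `term`, `estimate`, `se`, `t`, `p`, `stars`.
#' @export
coef_table <- function(fit, include_fe = FALSE) {
  stopifnot(inherits(fit, "diet_fit"))
  out <- fit$tidy
  if (!include_fe) out <- out[!out$fixed_effect, ]
  out[, c("term", "estimate", "se", "t", "p", "stars")]
}

#' @export
print.diet_fit <- function(x, digits = 3, ...) {
  cat(sprintf("OLS fit of %s (cluster-robust SEs on %s)\n",
              x$spec$outcome, x$spec$cluster))
  tb <- coef_table(x)
  cat(sprintf("  %-22s %10s %10s %s\n", "term", "estimate", "se", ""))
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-22s %10.*f %10.*f %s\n", tb$term[i], digits,
                tb$estimate[i], digits, tb$se[i], tb$stars[i]))
  }
  cat(sprintf("  County FE %s   N %d (dropped %d)\n",
              if (is.null(x$spec$fe)) "No" else "Yes", x$n, x$n_dropped))
  invisible(x)
}

#' Subgroup (heterogeneity) analysis
#'
#' Re-fits the main model within strata of a splitting variable. Cut
#' rules: `"median"` (Low/High at the empirical median), `"tercile"`
#' (Low/Middle/High at the empirical 33.3/66.7 percentiles), or
#' `"custom"` with explicit `thresholds` (strata are
#' `(-Inf, t1], (t1, t2], ..., (tk, Inf)`), which reproduces unequal
#' published splits such as 575/310/194. When the sample is split on
#' income in tercile mode, income is removed from the regressor list of
#' the stratum fits (its variation is what defines the strata).
#'
#' @inheritParams fit_main_model
#' @param split_var Column to split on (e.g. `"income"`,
#'   `"labor_number"`, `"ln_pension"`, `"food_market_density"`,
#'   `"ln_land"`).
#' @param cut Cut rule.
#' @param thresholds Numeric thresholds for `cut = "custom"`.
#' @param labels Optional stratum labels.
#' @param min_n Minimum rows per stratum (default 30); smaller strata are
#'   an error.
#' @return Object of class `diet_hetero`: named list of `diet_fit`s plus
#'   a combined coefficient table with a `stratum` column.
#' @export
run_heterogeneity <- function(data, spec, split_var,
                              cut = c("median", "tercile", "custom"),
                              thresholds = NULL, labels = NULL,
                              min_n = 30,
                              on_collinear = c("error", "drop")) {
  on_collinear <- match.arg(on_collinear)
  cut <- match.arg(cut)
  if (!split_var %in% names(data)) {
    stop("split variable not in data: ", split_var, call. = FALSE)
  }
  x <- data[[split_var]]
  brk <- switch(cut,
    median = quantile(x, 0.5, na.rm = TRUE, names = FALSE),
    tercile = quantile(x, c(1, 2) / 3, na.rm = TRUE, names = FALSE),
    custom = {
      if (is.null(thresholds)) {
        stop("cut = 'custom' needs `thresholds`.", call. = FALSE)
      }
      sort(thresholds)
    })
  if (is.null(labels)) {
    labels <- if (length(brk) == 1) c("Low", "High")
              else if (length(brk) == 2) c("Low", "Middle", "High")
              else paste0("S", seq_len(length(brk) + 1))
  }
  stratum <- cut(x, breaks = c(-Inf, brk, Inf), labels = labels,
                 right = TRUE)

  sspec <- spec
  if (split_var == "income" && cut == "tercile") {
    sspec$focal <- setdiff(sspec$focal, "income")
    sspec$controls <- setdiff(sspec$controls, "income")
  }

  fits <- lapply(levels(stratum), function(lv) {
    sub <- data[!is.na(stratum) & stratum == lv, , drop = FALSE]
    if (nrow(sub) < min_n) {
      stop(sprintf("stratum '%s' has %d rows, below the minimum of %d.",
                   lv, nrow(sub), min_n), call. = FALSE)
    }
    fit_main_model(sub, sspec, on_collinear = on_collinear)
  })
  names(fits) <- levels(stratum)
  combined <- dplyr::bind_rows(lapply(levels(stratum), function(lv) {
    dplyr::mutate(coef_table(fits[[lv]]), stratum = lv,
                  n = fits[[lv]]$n)
  }))
  structure(list(fits = fits, table = combined, split_var = split_var,
                 cut = cut, spec = sspec),
            class = "diet_hetero")
}

#' @export
print.diet_hetero <- function(x, digits = 3, ...) {
  cat(sprintf("Heterogeneity analysis of %s split by %s (%s)\n",
              x$spec$outcome, x$split_var, x$cut))
  focal <- c("(Intercept)", x$spec$focal)
  for (lv in names(x$fits)) {
    tb <- coef_table(x$fits[[lv]])
    tb <- tb[tb$term %in% focal, ]
    cat(sprintf("  [%s] N = %d\n", lv, x$fits[[lv]]$n))
    for (i in seq_len(nrow(tb))) {
      cat(sprintf("    %-16s %10.*f (%.*f)%s\n", tb$term[i], digits,
                  tb$estimate[i], digits, tb$se[i], tb$stars[i]))
    }
  }
  cat("  Controlled Yes   County FE",
      if (is.null(x$spec$fe)) "No" else "Yes", "\n")
  invisible(x)
}

#' Seemingly unrelated regressions with joint Wald tests
#'
#' Estimates one equation per outcome (the eight Pagoda-category intake
#' quantities in the published design), all sharing the same regressor
#' set, by one-step feasible GLS: equation-by-equation OLS, residual
#' cross-equation covariance (divisor `n - k`), then GLS on the stacked
#' system. For a named regressor, the joint Wald statistic tests that its
#' coefficient is zero in every equation, referred to chi-square with as
#' many degrees of freedom as equations. A (near-)singular residual
#' covariance falls back to its diagonal — equation-by-equation OLS —
#' with a warning.
#'
#' @param data Data frame holding outcomes and regressors.
#' @param outcomes Character vector of outcome columns (same rows
#'   observed for all of them).
#' @param regressors Character vector of shared regressors.
#' @param fe Optional fixed-effect factor column.
#' @param joint Regressors to run joint Wald tests for (default: all
#'   `regressors`).
#' @return Object of class `sur_fit`: coefficient and SE matrices
#'   (`k x m`), residual covariance `Sigma`, the FGLS covariance, joint
#'   Wald table, `n`.
#' @export
fit_sur <- function(data, outcomes, regressors, fe = NULL,
                    joint = regressors) {
  vars <- c(outcomes, regressors, fe)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, vars, drop = FALSE]
  cc <- stats::complete.cases(df[, c(regressors, fe), drop = FALSE])
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  m <- length(outcomes)
  Y <- as.matrix(df[, outcomes, drop = FALSE])
  if (anyNA(Y)) {
    stop("all outcomes must be observed on the same rows (unequal ",
         "effective row counts across equations).", call. = FALSE)
  }
  rhs <- regressors
  if (!is.null(fe)) {
    df[[fe]] <- factor(df[[fe]])
    rhs <- c(rhs, fe)
  }
  X <- model.matrix(stats::reformulate(rhs), data = df)
  k <- ncol(X)
  if (n <= k) stop("fewer rows than parameters.", call. = FALSE)

  XtX <- crossprod(X)
  B <- solve(XtX, crossprod(X, Y))          # per-equation OLS
  E <- Y - X %*% B
  Sigma <- crossprod(E) / (n - k)
  fallback <- FALSE
  if (rcond(Sigma) < 1e-12) {
    warning("residual covariance is (near-)singular; falling back to ",
            "equation-by-equation OLS (diagonal covariance).",
            call. = FALSE)
    Sigma <- diag(diag(Sigma), m)
    fallback <- TRUE
  }
  Sinv <- solve(Sigma)
  A <- kronecker(Sinv, XtX)                 # stacked GLS normal matrix
  rhs_vec <- as.vector(XtX %*% B %*% Sinv)  # vec(X'Y Sigma^-1)
  beta <- solve(A, rhs_vec)
  V <- solve(A)                             # = Sigma (x) (X'X)^-1
  coefs <- matrix(beta, nrow = k, dimnames = list(colnames(X), outcomes))
  ses <- matrix(sqrt(diag(V)), nrow = k,
                dimnames = list(colnames(X), outcomes))

  XtXinv <- solve(XtX)
  wald <- dplyr::bind_rows(lapply(joint, function(r) {
    if (!r %in% rownames(coefs)) {
      stop("joint-test regressor not in design: ", r, call. = FALSE)
    }
    br <- coefs[r, ]
    Vrr <- Sigma * XtXinv[r, r]
    W <- drop(crossprod(br, solve(Vrr, br)))
    tibble::tibble(term = r, wald = W, df = m,
                   p = stats::pchisq(W, m, lower.tail = FALSE),
                   stars = significance_stars(
                     stats::pchisq(W, m, lower.tail = FALSE)))
  }))

  structure(list(coefficients = coefs, se = ses, Sigma = Sigma,
                 vcov = V, wald = wald, n = n, k = k,
                 outcomes = outcomes, fallback_diagonal = fallback),
            class = "sur_fit")
}

#' @export
print.sur_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SUR system: %d equations, N = %d\n",
              length(x$outcomes), x$n))
  show <- setdiff(rownames(x$coefficients),
                  grep("^(\\(Intercept\\)|county_id|.*_id)",
                       rownames(x$coefficients), value = TRUE))
  show <- head(show, 6)
  for (r in show) {
    cat(sprintf("  %-16s %s\n", r,
                paste(sprintf("%.*f", digits, x$coefficients[r, ]),
                      collapse = "  ")))
  }
  cat("  Joint Wald tests:\n")
  for (i in seq_len(nrow(x$wald))) {
    cat(sprintf("    %-16s chi2(%d) = %.2f%s\n", x$wald$term[i],
                x$wald$df[i], x$wald$wald[i], x$wald$stars[i]))
  }
  invisible(x)
}

#' LASSO with 10-fold cross-validation
#'
#' L1-penalized least squares over a decreasing penalty grid with
#' cross-validated penalty selection (the robustness design of the study:
#' `glmnet` with 10-fold CV). Predictors are standardized internally;
#' folds are assigned by a seeded permutation so the check is
#' reproducible. The selected penalty minimizes CV error
#' (`selection = "min"`, default) or applies the one-standard-error rule
#' (`selection = "1se"`).
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param predictors Candidate predictor columns.
#' @param nfolds Number of CV folds (default 10, >= 2).
#' @param seed Integer seed for the fold permutation.
#' @param lambda Optional explicit penalty grid (on the `glmnet` scale);
#'   default 100 log-spaced values down to `1e-4` of the smallest
#'   all-zero penalty.
#' @param selection Penalty selection rule.
#' @return Object of class `diet_lasso`: penalty grid, coefficient path,
#'   CV curve, selected penalty, surviving predictors, fold assignment.
#' @export
fit_lasso_cv <- function(data, outcome, predictors, nfolds = 10,
                         seed = 1L, lambda = NULL,
                         selection = c("min", "1se")) {
  selection <- match.arg(selection)
  if (nfolds < 2) stop("need at least 2 folds.", call. = FALSE)
  df <- data[, c(outcome, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < nfolds) stop("fewer rows than folds.", call. = FALSE)
  x <- as.matrix(df[, predictors, drop = FALSE])
  y <- df[[outcome]]
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cvfit <- glmnet::cv.glmnet(x, y, foldid = foldid, lambda = lambda,
                             nlambda = 100, lambda.min.ratio = 1e-4,
                             standardize = TRUE)
  sel <- if (selection == "min") cvfit$lambda.min else cvfit$lambda.1se
  b <- coef(cvfit, s = sel)
  nz <- rownames(b)[as.vector(b != 0)]
  structure(list(
    lambda = cvfit$lambda, cvm = cvfit$cvm, cvsd = cvfit$cvsd,
    beta_path = as.matrix(cvfit$glmnet.fit$beta),
    lambda_min = cvfit$lambda.min, lambda_1se = cvfit$lambda.1se,
    selected_lambda = sel, selection = selection,
    coefficients = setNames(as.vector(b), rownames(b)),
    survivors = setdiff(nz, "(Intercept)"),
    foldid = foldid, n = n, cvfit = cvfit),
    class = "diet_lasso")
}

#' @export
print.diet_lasso <- function(x, ...) {
  cat(sprintf("LASSO (%d-fold CV, n = %d): selected lambda = %.4g (%s)\n",
              max(x$foldid), x$n, x$selected_lambda, x$selection))
  cat("  surviving predictors:",
      if (length(x$survivors)) paste(x$survivors, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
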