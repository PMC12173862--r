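# Scenario projection of the dietary-health indices under joint
# population-aging and income-growth paths.

#' Aging and income-growth scenario
#'
#' Describes a projection horizon with geometric growth of the elderly
#' household-member share (annual rate `m`) and of per-capita income
#' (annual rate `n`): `ratio_t = ratio_{t-1} * (1 + m)`,
#' `income_t = income_{t-1} * (1 + n)`. Because an "annual growth of
#' 1.03%" can also be read as an annual increment of 1.03 percentage
#' points (which yields a linear, much steeper aging path),
#' `growth_mode = "linear_increment"` applies
#' `ratio_t = ratio_0 + 100 * m * (t - t0)` instead; neither reading is
#' endorsed and both can be reported side by side. Income always grows
#' geometrically.
#'
#' @param start_year,end_year Projection window (default 2023-2050).
#' @param ratio0 Elderly share at the start year, percent.
#' @param m Annual aging growth rate (e.g. `0.0103`).
#' @param income0 Per-capita income at the start year, 10^4 Yuan.
#' @param n Annual income growth rate (0, 0.025, 0.05, 0.075 in the
#'   published scenarios).
#' @param growth_mode `"multiplicative"` (default) or
#'   `"linear_increment"` for the aging path.
#' @return Object of class `scenario`.
#' @export
scenario <- function(start_year = 2023, end_year = 2050, ratio0 = 20,
                     m = 0.0103, income0 = 2.53, n = 0.05,
                     growth_mode = c("multiplicative",
                                     "linear_increment")) {
  growth_mode <- match.arg(growth_mode)
  if (end_year < start_year) {
    stop("end_year must be >= start_year.", call. = FALSE)
  }
  if (ratio0 < 0 || ratio0 > 100) {
    stop("ratio0 must be a percentage in [0, 100].", call. = FALSE)
  }
  if (income0 < 0) stop("income0 must be non-negative.", call. = FALSE)
  structure(list(start_year = start_year, end_year = end_year,
                 ratio0 = ratio0, m = m, income0 = income0, n = n,
                 growth_mode = growth_mode),
            class = "scenario")
}

#' Project the aging and income driver series
#'
#' Runs the year-by-year recursion of the scenario. The elderly share is
#' capped at 100% with a warning if the path ever exceeds it.
#'
#' @param scn A [scenario()].
#' @return Tibble with columns `year`, `ratio` (percent), `income`
#'   (10^4 Yuan).
#' @export
#' @examples
#' project_drivers(scenario(ratio0 = 20, m = 0.0103, n = 0))
project_drivers <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  years <- scn$start_year:scn$end_year
  steps <- length(years)
  ratio <- numeric(steps); income <- numeric(steps)
  ratio[1] <- scn$ratio0; income[1] <- scn$income0
  for (i in seq_len(steps - 1)) {
    ratio[i + 1] <- if (scn$growth_mode == "multiplicative") {
      ratio[i] * (1 + scn$m)
    } else {
      scn$ratio0 + 100 * scn$m * i
    }
    income[i + 1] <- income[i] * (1 + scn$n)
  }
  if (any(ratio > 100)) {
    warning("projected elderly share exceeds 100%; capped.",
            call. = FALSE)
    ratio <- pmin(ratio, 100)
  }
  tibble::tibble(year = years, ratio = ratio, income = income)
}

#' Evaluate an index trajectory over a driver series
#'
#' Linear extrapolation `y_t = alpha + beta * ratio_t + gamma * income_t`
#' evaluated exactly at every year: `alpha` is the regression constant,
#' `beta` the aging (over-65 share) coefficient and `gamma` the income
#' coefficient, typically taken from a fitted main model. Projections are
#' unconstrained by default; supply `clip_range` (e.g. `c(0, log(12))`)
#' to clamp to the index's admissible range, in which case clamped years
#' are flagged.
#'
#' @param coeffs Named numeric vector `c(alpha, beta, gamma)` (names
#'   optional, order fixed).
#' @param drivers Tibble from [project_drivers()].
#' @param clip_range Optional length-2 numeric range.
#' @return Tibble `year`, `ratio`, `income`, `y` (and `clipped` when a
#'   range is supplied).
#' @export
#' @examples
#' d <- project_drivers(scenario())
#' project_index(c(alpha = 0.693, beta = -0.001, gamma = 0.017), d)
project_index <- function(coeffs, drivers, clip_range = NULL) {
  if (length(coeffs) != 3 || anyNA(coeffs)) {
    stop("`coeffs` must be (alpha, beta, gamma) with no NAs.",
         call. = FALSE)
  }
  y <- coeffs[[1]] + coeffs[[2]] * drivers$ratio +
    coeffs[[3]] * drivers$income
  out <- dplyr::mutate(drivers, y = y)
  if (!is.null(clip_range)) {
    stopifnot(length(clip_range) == 2)
    out$clipped <- y < clip_range[1] | y > clip_range[2]
    out$y <- pmin(pmax(y, clip_range[1]), clip_range[2])
  }
  out
}

#' Extract projection coefficients from a fitted main model
#'
#' Pulls `(alpha, beta, gamma)` — the constant, the over-65 share
#' coefficient and the income coefficient — from a [fit_main_model()]
#' result, for use with [project_index()].
#'
#' @param fit A `diet_fit`.
#' @param aging_term,income_term Coefficient names to extract.
#' @return Named numeric vector `c(alpha, beta, gamma)`.
#' @export
projection_coefs <- function(fit, aging_term = "ratio_over65",
                             income_term = "income") {
  stopifnot(inherits(fit, "diet_fit"))
  est <- coef(fit$model)
  need <- c("(Intercept)", aging_term, income_term)
  if (!all(need %in% names(est))) {
    stop("fit lacks coefficient(s): ",
         paste(setdiff(need, names(est)), collapse = ", "), call. = FALSE)
  }
  c(alpha = unname(est["(Intercept)"]), beta = unname(est[aging_term]),
    gamma = unname(est[income_term]))
}

#' Trajectories over a grid of income growth rates
#'
#' One trajectory per income growth rate, sharing the base scenario's
#' aging path — the published scenario design (no growth, 2.5%, 5%,
#' 7.5%). With a positive income coefficient the terminal index values
#' are strictly increasing in the growth rate.
#'
#' @inheritParams project_index
#' @param base A [scenario()] supplying the horizon and aging path.
#' @param n_values Income growth rates (non-empty).
#' @return Tibble with an extra `scenario` column (`"n=2.5%"`, ...).
#' @export
scenario_grid <- function(coeffs, base = scenario(),
                          n_values = c(0, 0.025, 0.05, 0.075),
                          clip_range = NULL) {
  if (!length(n_values)) stop("n_values must be non-empty.", call. = FALSE)
  dplyr::bind_rows(lapply(n_values, function(nv) {
    scn <- base
    scn$n <- nv
    dplyr::mutate(project_index(coeffs, project_drivers(scn), clip_range),
                  scenario = sprintf("n=%g%%", 100 * nv))
  }))
}

#' Plot a scenario grid
#'
#' Line plot of projected index trajectories, one line per income-growth
#' scenario. Requires ggplot2.
#'
#' @param grid Tibble from [scenario_grid()].
#' @param ylab Axis label for the index.
#' @return A ggplot object.
#' @export
plot_projection <- function(grid, ylab = "index") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting.", call. = FALSE)
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$year, y = .data$y,
                                     colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "year", y = ylab, colour = "income growth") +
    ggplot2::theme_minimal()
}
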