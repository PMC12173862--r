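#' Stratified survey design
#'
#' Describes the nested sampling frame of the survey: provinces, counties
#' within province, townships within county, villages within township, and
#' households within village, each household observed for `days`
#' consecutive days. The default reproduces the study design of the
#' source survey: 3 provinces x 4 counties x 3 townships x 3 villages x
#' 10 households = 1,080 households in 108 villages, observed for 3 days.
#'
#' @param provinces,counties_per_province,townships_per_county,villages_per_township,households_per_village
#'   Positive integer design counts.
#' @param days Number of consecutive survey days (default 3).
#' @param seed Default integer seed used by [generate_survey()].
#' @return Object of class `survey_design`.
#' @export
#' @examples
#' survey_design()          # the default 1,080-household frame
#' survey_design(1, 1, 1, 1, 1)  # degenerate single-household design
survey_design <- function(provinces = 3, counties_per_province = 4,
                          townships_per_county = 3,
                          villages_per_township = 3,
                          households_per_village = 10,
                          days = 3, seed = 1L) {
  counts <- c(provinces = provinces,
              counties_per_province = counties_per_province,
              townships_per_county = townships_per_county,
              villages_per_township = villages_per_township,
              households_per_village = households_per_village,
              days = days)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be positive integers.", call. = FALSE)
  }
  structure(c(as.list(counts), list(seed = as.integer(seed))),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Stratified survey design:\n")
  cat(sprintf("  %d provinces x %d counties x %d townships x %d villages x %d households\n",
              x$provinces, x$counties_per_province, x$townships_per_county,
              x$villages_per_township, x$households_per_village))
  cat(sprintf("  = %d households in %d villages, %d survey days\n",
              n_households(x), n_villages(x), x$days))
  invisible(x)
}

n_counties <- function(design) design$provinces * design$counties_per_province
n_villages <- function(design) {
  n_counties(design) * design$townships_per_county *
    design$villages_per_township
}
n_households <- function(design) {
  n_villages(design) * design$households_per_village
}

#' Planted linear effect specification for one outcome index
#'
#' Generator-side counterpart of the outcome regression: the latent index
#' level for each household is drawn as
#' `intercept + beta_under18 * ratio_under18 + beta_over65 * ratio_over65 +
#' gamma_income * income + sum(control_betas * controls) + county effect +
#' noise`. Ratios are in percentage points and income in 10^4 Yuan, so
#' `beta_*` are per-percentage-point and `gamma_income` per-10^4-Yuan
#' effects in index units.
#'
#' @param outcome One of `"EI"`, `"CFPS"`, `"CHEI"`.
#' @param intercept Index units.
#' @param beta_under18,beta_over65 Effects per percentage point of the
#'   under-18 / over-65 member share.
#' @param gamma_income Effect per 10^4 Yuan of per-capita income.
#' @param control_betas Named numeric vector of effects for control
#'   regressors (names must match regressor-frame columns, e.g.
#'   `dki`, `ln_pension`).
#' @param noise_sd Household-level noise SD, index units (> 0).
#' @param county_sd SD of i.i.d. normal county effects, index units
#'   (the generator-side counterpart of county fixed effects).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(outcome, intercept, beta_under18 = 0,
                        beta_over65 = 0, gamma_income = 0,
                        control_betas = numeric(), noise_sd = 1,
                        county_sd = 0) {
  outcome <- match.arg(outcome, c("EI", "CFPS", "CHEI"))
  if (noise_sd <= 0) stop("noise_sd must be > 0.", call. = FALSE)
  if (county_sd < 0) stop("county_sd must be >= 0.", call. = FALSE)
  if (length(control_betas) &&
      (is.null(names(control_betas)) || any(names(control_betas) == ""))) {
    stop("control_betas must be a named numeric vector.", call. = FALSE)
  }
  structure(list(outcome = outcome, intercept = intercept,
                 beta_under18 = beta_under18, beta_over65 = beta_over65,
                 gamma_income = gamma_income,
                 control_betas = control_betas,
                 noise_sd = noise_sd, county_sd = county_sd),
            class = "effect_spec")
}

#' Default planted effects for the three indices
#'
#' The default effect specifications reproduce the published sign pattern
#' and magnitudes of the study's main regression table: a small positive
#' under-18 effect on diversity, a negative over-65 (aging) effect on all
#' three indices, and a positive income effect on all three. Noise SDs
#' are set so the simulated index dispersions are of the same order as the
#' reported descriptive SDs.
#'
#' @return Named list of [effect_spec()] objects for `EI`, `CFPS`, `CHEI`.
#' @export
default_effects <- function() {
  list(
    EI = effect_spec(
      "EI", intercept = 0.693,
      beta_under18 = 0.002, beta_over65 = -0.001, gamma_income = 0.017,
      control_betas = c(gender_dm = 0.027, married_dm = 0.031,
                        education_dm = 0.058, dki = 0.012,
                        ln_pension = 0.109, off_farm = -0.032,
                        ln_distance = 0.002, ln_land = 0.008,
                        crop_diversity = 0.000, household_size = 0.013,
                        property = 0.000, village_population = 0.000,
                        village_distance = -0.002,
                        food_market_density = 0.001,
                        ln_village_income = 0.040,
                        ln_village_land = 0.037),
      noise_sd = 0.25, county_sd = 0.05),
    CFPS = effect_spec(
      "CFPS", intercept = 1.064,
      beta_under18 = 0.000, beta_over65 = -0.002, gamma_income = 0.025,
      control_betas = c(gender_dm = 0.188, married_dm = -0.047,
                        education_dm = 0.269, dki = 0.067,
                        ln_pension = 0.299, off_farm = -0.015,
                        ln_distance = -0.025, ln_land = 0.022,
                        crop_diversity = 0.025, household_size = 0.048,
                        property = 0.000, village_population = 0.000,
                        village_distance = -0.008,
                        food_market_density = 0.004,
                        ln_village_income = 0.021,
                        ln_village_land = 0.072),
      noise_sd = 0.9, county_sd = 0.2),
    CHEI = effect_spec(
      "CHEI", intercept = 17.373,
      beta_under18 = 0.006, beta_over65 = -0.016, gamma_income = 0.139,
      control_betas = c(gender_dm = 0.933, married_dm = 0.134,
                        education_dm = 1.553, dki = 0.329,
                        ln_pension = 2.399, off_farm = -0.065,
                        ln_distance = 0.023, ln_land = -0.055,
                        crop_diversity = 0.139, household_size = 0.332,
                        property = -0.008, village_population = 0.000,
                        village_distance = -0.027,
                        food_market_density = -0.005,
                        ln_village_income = -0.720,
                        ln_village_land = 0.311),
      noise_sd = 5.5, county_sd = 1.0)
  )
}

#' Default marginal calibration moments for the generator
#'
#' Target means/SDs and distributional knobs for every covariate the
#' generator draws, set to the descriptive statistics reported for the
#' source survey (means such as 26.61% of members aged 65+ and per-capita
#' income 2.53 x 10^4 Yuan). Right-skewed non-negative variables use
#' log-normal marginals parameterized to hit the target mean and SD
#' exactly; binary variables use Bernoulli; counts use shifted Poisson.
#'
#' @return Named list of calibration settings; edit fields to move the
#'   generator away from the study conditions.
#' @export
default_calibration <- function() {
  list(
    # expected member-age mixture (under-18 / 18-65 / 65+) and the
    # Dirichlet concentration controlling between-household heterogeneity
    age_mix = c(under18 = 0.0917, adult = 0.6346, over65 = 0.2661),
    age_alpha = 1.3,
    household_size_mean = 3.16,   # 1 + Poisson(mean - 1)
    income = c(mean = 2.53, sd = 2.51),       # 10^4 Yuan, log-normal
    gender_p = 0.78, married_p = 0.91, education_p = 0.03,
    dki_items = 9L, dki_mean = 7.11,          # Binomial(9, mean/9)
    pension = list(p_zero = 0.6, mean = 0.475, sd = 0.6),  # 10^4 Yuan
    off_farm = c(mean = 0.35, sd = 0.32),     # Beta on [0, 1]
    distance = c(mean = 3.02, sd = 3.80),     # km, log-normal
    land = c(mean = 0.34, sd = 0.44),         # ha per capita, log-normal
    crop_diversity_mean = 5.66,               # 1 + Poisson(mean - 1)
    property = c(mean = 16.09, sd = 36.52),   # 10^4 Yuan, log-normal
    village_population = c(mean = 900.95, sd = 616.59),
    village_distance = c(mean = 5.45, sd = 5.77),
    food_market_density = c(mean = 13.73, sd = 10.94),
    village_income = c(mean = 1.63, sd = 0.61),
    village_land = c(mean = 322.73, sd = 313.15),
    # consumption/ledger knobs
    meals_per_day = 3,
    meal_skip_p = 0.1,        # chance a member's meal is away from home
    guest_meal_mean = 0.3,    # Poisson mean of guest person-meals per day
    # probability each food group is a household's dominant staple
    staple_probs = c(cereals = 0.45, tubers = 0.05, dried_legumes = 0.02,
                     vegetables = 0.25, fungi_algae = 0.01, fruits = 0.04,
                     nuts_seeds = 0.01, meat = 0.08, poultry = 0.03,
                     dairy = 0.02, eggs = 0.02, aquatic = 0.02)
  )
}
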