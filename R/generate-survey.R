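# Synthetic survey generator: covariates, meal ledgers and consumption
# records with the nested sampling frame and planted index effects.

# log-normal parameters hitting a target mean and SD exactly
lnorm_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_cal <- function(n, moments) {
  p <- lnorm_pars(moments[["mean"]], moments[["sd"]])
  rlnorm(n, p$meanlog, p$sdlog)
}

rbeta_cal <- function(n, moments) {
  m <- moments[["mean"]]; v <- moments[["sd"]]^2
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, m * k, (1 - m) * k)
}

#' Age-composition shares of a household
#'
#' Converts a vector of member ages into the three family-composition
#' percentages: members under 18, aged 18-65, and 65 and above. The three
#' shares always sum to 100.
#'
#' @param ages Integer vector of member ages (years), length >= 1.
#' @return Named numeric vector
#'   `c(ratio_under18, ratio_18_65, ratio_over65)` in percent.
#' @export
#' @examples
#' composition_ratios(c(10, 40, 42, 70))  # 25 / 50 / 25
composition_ratios <- function(ages) {
  if (length(ages) < 1 || any(ages < 0)) {
    stop("need at least one non-negative age.", call. = FALSE)
  }
  n <- length(ages)
  c(ratio_under18 = 100 * sum(ages < 18) / n,
    ratio_18_65  = 100 * sum(ages >= 18 & ages < 65) / n,
    ratio_over65 = 100 * sum(ages >= 65) / n)
}

# draw member ages from a child/adult/elderly mixture whose household-level
# class profile is Dirichlet-distributed around `mix` (concentration
# `alpha`), giving the strong between-household heterogeneity seen in
# rural samples (many all-elderly and no-child households)
draw_household_ages <- function(size, mix, alpha = 1.3) {
  stopifnot(size >= 1)
  g <- rgamma(3, shape = alpha * mix)
  if (sum(g) <= 0) g <- mix
  phi <- g / sum(g)
  counts <- as.vector(stats::rmultinom(1, size, phi))
  c(if (counts[1]) sample(0:17, counts[1], replace = TRUE),
    if (counts[2]) sample(18:64, counts[2], replace = TRUE),
    if (counts[3]) sample(65:90, counts[3], replace = TRUE))
}

#' Draw one household's age composition
#'
#' Samples integer member ages from the calibrated child/adult/elderly
#' mixture and returns the three composition percentages.
#'
#' @param household_size Number of members (>= 1).
#' @param age_mix Expected class shares (under-18, 18-65, 65+), summing
#'   to 1.
#' @param age_alpha Dirichlet concentration of the household-level class
#'   profile; smaller values give more extreme households.
#' @return Named numeric vector of three percentages summing to 100.
#' @export
plant_composition <- function(household_size,
                              age_mix = default_calibration()$age_mix,
                              age_alpha = default_calibration()$age_alpha) {
  if (household_size < 1) stop("household_size must be >= 1.", call. = FALSE)
  composition_ratios(draw_household_ages(household_size, age_mix, age_alpha))
}

# Shannon entropy of the evenness mixture w = lambda/12 + (1-lambda)*e_d.
# Scalar in lambda and independent of which group is dominant.
mixture_entropy <- function(lambda) {
  wd <- 1 - 11 * lambda / 12
  wo <- lambda / 12
  -(11 * ifelse(wo > 0, wo * log(wo), 0) + ifelse(wd > 0, wd * log(wd), 0))
}

# vectorized bisection: evenness lambda such that the mixture entropy hits
# each target (targets in (0, log(12)))
solve_entropy_evenness <- function(target) {
  lo <- rep(0, length(target)); hi <- rep(1, length(target))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    too_low <- mixture_entropy(mid) < target
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
  }
  (lo + hi) / 2
}

# vectorized bisection: total grams/person/day T such that the adequacy
# healthy-eating index of intake T * w hits each target; requires an
# adequacy-only component table (the score is then monotone in T)
solve_chei_scale <- function(w, components, target) {
  if (any(components$kind != "adequacy")) {
    stop("the generator can only invert the healthy-eating index for an ",
         "adequacy-only component table (score must be monotone in the ",
         "total-quantity scale).", call. = FALSE)
  }
  R <- components$R[match(food_groups(), components$component)]
  chei_of <- function(logT) {
    5 * rowSums(pmin(sweep(w * exp(logT), 2, R, "/"), 1))
  }
  lo <- rep(log(1e-3), nrow(w)); hi <- rep(log(1e8), nrow(w))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    too_low <- chei_of(mid) < target
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
  }
  exp((lo + hi) / 2)
}

#' Generate a complete synthetic survey
#'
#' Draws household covariates, at-home meal ledgers and day-by-day
#' food-group consumption records under the nested sampling frame of
#' `design`, with index effects planted according to `effects`. The
#' generator works backwards from latent index targets: for each
#' household a target diversity level (EI) and a target diet-quality
#' level (CHEI) are drawn from their linear effect models (plus i.i.d.
#' county effects and noise); an evenness parameter and a total-quantity
#' scale are then solved by bisection so the scored consumption
#' reproduces those targets exactly. The Pagoda score (CFPS) is emergent:
#' it is computed from the same consumption and inherits the planted
#' structure through the induced adherence rather than being separately
#' controlled (one consumption vector cannot pin three indices at once).
#'
#' Identical `(design, effects, calibration, seed)` give identical output.
#'
#' @param design A [survey_design()].
#' @param effects Named list of [effect_spec()] objects; specs for `EI`
#'   and `CHEI` drive the construction (see above).
#' @param calibration Marginal calibration list, see
#'   [default_calibration()].
#' @param components Adequacy component table used to invert the target
#'   diet-quality score; see [default_chei_components()].
#' @param seed Integer seed; defaults to the design's seed.
#' @return Object of class `rural_survey`: a list with tibbles
#'   `covariates` (one row per household), `meals` (household x day),
#'   `consumption` (household x day x food group, edible grams), and
#'   `truth` (the latent index targets, for validation studies).
#' @export
#' @examples
#' svy <- generate_survey(survey_design(1, 1, 1, 2, 5), seed = 7)
#' nrow(svy$covariates)
generate_survey <- function(design = survey_design(),
                            effects = default_effects(),
                            calibration = default_calibration(),
                            components = default_chei_components(),
                            seed = design$seed) {
  stopifnot(inherits(design, "survey_design"))
  for (e in effects) stopifnot(inherits(e, "effect_spec"))
  if (!all(c("EI", "CHEI") %in% names(effects))) {
    stop("`effects` must contain specs for at least EI and CHEI.",
         call. = FALSE)
  }
  set.seed(seed)
  cal <- calibration
  n  <- n_households(design)
  nv <- n_villages(design)
  nc <- n_counties(design)
  days <- design$days
  mpd <- cal$meals_per_day

  village_of <- rep(seq_len(nv), each = design$households_per_village)
  county_of  <- rep(seq_len(nc),
                    each = design$townships_per_county *
                      design$villages_per_township *
                      design$households_per_village)
  hid <- sprintf("h%05d", seq_len(n))

  ## --- covariates -------------------------------------------------------
  size <- 1L + rpois(n, cal$household_size_mean - 1)
  comp <- t(vapply(size, plant_composition, numeric(3),
                   age_mix = cal$age_mix, age_alpha = cal$age_alpha))
  income <- rlnorm_cal(n, cal$income)
  pension <- ifelse(runif(n) < cal$pension$p_zero, 0,
                    rlnorm(n, lnorm_pars(cal$pension$mean,
                                         cal$pension$sd)$meanlog,
                           lnorm_pars(cal$pension$mean,
                                      cal$pension$sd)$sdlog))

  vill <- tibble::tibble(
    village_idx = seq_len(nv),
    village_population = round(rlnorm_cal(nv, cal$village_population)),
    village_distance = rlnorm_cal(nv, cal$village_distance),
    food_market_density = round(rlnorm_cal(nv, cal$food_market_density)),
    village_income = rlnorm_cal(nv, cal$village_income),
    village_land = rlnorm_cal(nv, cal$village_land)
  )

  covariates <- tibble::tibble(
    household_id = hid,
    village_id = sprintf("v%04d", village_of),
    county_id = sprintf("c%02d", county_of),
    ratio_under18 = comp[, 1],
    ratio_18_65 = comp[, 2],
    ratio_over65 = comp[, 3],
    income = income,
    gender_dm = rbinom(n, 1, cal$gender_p),
    married_dm = rbinom(n, 1, cal$married_p),
    education_dm = rbinom(n, 1, cal$education_p),
    dki = rbinom(n, cal$dki_items, cal$dki_mean / cal$dki_items),
    pension = pension,
    off_farm = rbeta_cal(n, cal$off_farm),
    distance_km = rlnorm_cal(n, cal$distance),
    land_ha = rlnorm_cal(n, cal$land),
    crop_diversity = 1L + rpois(n, cal$crop_diversity_mean - 1),
    household_size = size,
    property = rlnorm_cal(n, cal$property)
  )
  covariates <- dplyr::left_join(
    dplyr::mutate(covariates, village_idx = village_of), vill,
    by = "village_idx") |>
    dplyr::select(-"village_idx")

  ## --- latent index targets --------------------------------------------
  rf <- regressor_frame(covariates)
  latent <- function(spec) {
    mu <- spec$intercept +
      spec$beta_under18 * rf$ratio_under18 +
      spec$beta_over65 * rf$ratio_over65 +
      spec$gamma_income * rf$income
    if (length(spec$control_betas)) {
      unknown <- setdiff(names(spec$control_betas), names(rf))
      if (length(unknown)) {
        stop("effect spec references unknown covariate(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      mu <- mu + as.matrix(rf[, names(spec$control_betas)]) %*%
        spec$control_betas
    }
    county_eff <- rnorm(nc, 0, spec$county_sd)
    drop(mu) + county_eff[county_of] + rnorm(n, 0, spec$noise_sd)
  }
  ei_target <- pmin(pmax(latent(effects$EI), 0.02), log(12) - 0.02)
  chei_target <- pmin(pmax(latent(effects$CHEI), 0.5), 59.5)

  ## --- consumption consistent with the targets -------------------------
  lambda <- solve_entropy_evenness(ei_target)
  dominant <- sample(food_groups(), n, replace = TRUE,
                     prob = cal$staple_probs[food_groups()])
  w <- matrix(rep(lambda / 12, 12), nrow = n)
  colnames(w) <- food_groups()
  w[cbind(seq_len(n), match(dominant, food_groups()))] <-
    lambda / 12 + (1 - lambda)
  total_scale <- solve_chei_scale(w, components, chei_target)
  intake <- w * total_scale                      # grams/person/day

  ## --- meal ledger ------------------------------------------------------
  fam <- matrix(rbinom(n * days, rep(size, days) * mpd,
                       1 - cal$meal_skip_p), nrow = n)
  guests <- matrix(rpois(n * days, cal$guest_meal_mean), nrow = n)
  empty <- rowSums(fam) + rowSums(guests) == 0
  fam[empty, 1] <- size[empty] * mpd
  person_days <- (rowSums(fam) + rowSums(guests)) / mpd

  meals <- tibble::tibble(
    household_id = rep(hid, days),
    day = rep(seq_len(days), each = n),
    family_person_meals = as.vector(fam),
    guest_person_meals = as.vector(guests)
  ) |> dplyr::arrange(.data$household_id, .data$day)

  ## --- split totals over days ------------------------------------------
  dg <- matrix(rgamma(n * days, 8), nrow = n)
  day_share <- dg / rowSums(dg)
  total_g <- intake * person_days                # grams over the 3 days
  A <- array(0, c(n, days, 12))
  for (d in seq_len(days)) A[, d, ] <- total_g * day_share[, d]
  consumption <- tibble::tibble(
    household_id = rep(hid, each = days * 12),
    day = rep(rep(seq_len(days), each = 12), n),
    food_group = rep(food_groups(), n * days),
    grams = as.vector(aperm(A, c(3, 2, 1)))
  )

  truth <- tibble::tibble(household_id = hid,
                          EI_target = ei_target,
                          CHEI_target = chei_target)
  structure(list(covariates = covariates, meals = meals,
                 consumption = consumption, truth = truth,
                 design = design, seed = seed),
            class = "rural_survey")
}

#' @export
print.rural_survey <- function(x, ...) {
  cat("Synthetic rural food-consumption survey\n")
  print(x$design)
  cat(sprintf("  seed %d; %d consumption records, %d ledger rows\n",
              x$seed, nrow(x$consumption), nrow(x$meals)))
  invisible(x)
}

#' Write / read a survey as plain CSV files
#'
#' Persists the three survey tables as UTF-8 CSVs with header rows:
#' `consumption.csv`, `meals.csv`, `covariates.csv`. Re-running the
#' generator with the same seed reproduces the files byte for byte.
#'
#' @param survey A `rural_survey` object (or any list with the three
#'   tibbles).
#' @param dir Directory to write into (created if missing).
#' @return `write_survey()` returns the paths invisibly; `read_survey()`
#'   returns a list of the three tibbles.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("consumption.csv", "meals.csv",
                            "covariates.csv"))
  readr::write_csv(survey$consumption, paths[1])
  readr::write_csv(survey$meals, paths[2])
  readr::write_csv(survey$covariates, paths[3])
  invisible(paths)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  list(
    consumption = readr::read_csv(file.path(dir, "consumption.csv"),
                                  show_col_types = FALSE),
    meals = readr::read_csv(file.path(dir, "meals.csv"),
                            show_col_types = FALSE),
    covariates = readr::read_csv(file.path(dir, "covariates.csv"),
                                 show_col_types = FALSE)
  )
}
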