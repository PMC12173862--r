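#' Standardize household consumption to grams per person-day
#'
#' Converts 3-day household consumption records into per-capita daily
#' intakes using the at-home meal ledger. The denominator is the number of
#' person-days actually eaten at home: family and guest person-meals are
#' summed over the survey days and divided by the number of meals per day.
#' This corrects both for household size and for meals eaten away from
#' home (and for guests, which would otherwise inflate apparent intake).
#'
#' Duplicate `(household_id, day, food_group)` rows are summed before
#' standardization; food groups absent from the records get intake 0.
#'
#' @param consumption Data frame with columns `household_id`, `day`,
#'   `food_group`, `grams` (edible weight).
#' @param meals Data frame with columns `household_id`, `day`,
#'   `family_person_meals`, `guest_person_meals`.
#' @param meals_per_day Meals per day used to convert person-meals into
#'   person-days (default 3).
#' @return Tibble with one row per household: `household_id`,
#'   `person_days`, and one intake column (grams/person/day) per food
#'   group in canonical order.
#' @export
#' @examples
#' cons <- tibble::tibble(household_id = "h1", day = 1,
#'                        food_group = "vegetables", grams = 9000)
#' ml <- tibble::tibble(household_id = "h1", day = 1:3,
#'                      family_person_meals = 9, guest_person_meals = 0)
#' standardize_intake(cons, ml)  # 9000 g over 9 person-days -> 1000 g
standardize_intake <- function(consumption, meals, meals_per_day = 3) {
  stopifnot(meals_per_day >= 1)
  need_c <- c("household_id", "day", "food_group", "grams")
  need_m <- c("household_id", "day", "family_person_meals",
              "guest_person_meals")
  if (!all(need_c %in% names(consumption))) {
    stop("`consumption` needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_m %in% names(meals))) {
    stop("`meals` needs columns: ", paste(need_m, collapse = ", "),
         call. = FALSE)
  }
  if (any(consumption$grams < 0)) {
    stop("negative grams in consumption records.", call. = FALSE)
  }
  bad_group <- setdiff(unique(consumption$food_group), food_groups())
  if (length(bad_group)) {
    stop("unknown food group(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (any(meals$family_person_meals < 0 | meals$guest_person_meals < 0)) {
    stop("person-meal counts must be non-negative.", call. = FALSE)
  }

  pd <- meals |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(
      person_days = sum(.data$family_person_meals +
                          .data$guest_person_meals) / meals_per_day,
      .groups = "drop"
    )
  if (any(pd$person_days <= 0)) {
    stop("zero total person-meals for household(s): ",
         paste(pd$household_id[pd$person_days <= 0], collapse = ", "),
         "; per-capita intake is undefined.", call. = FALSE)
  }

  totals <- consumption |>
    dplyr::group_by(.data$household_id, .data$food_group) |>
    dplyr::summarise(grams = sum(.data$grams), .groups = "drop")

  wide <- totals |>
    tidyr::pivot_wider(names_from = "food_group", values_from = "grams",
                       values_fill = 0)
  for (g in setdiff(food_groups(), names(wide))) wide[[g]] <- 0

  out <- dplyr::inner_join(pd, wide, by = "household_id")
  missing_hh <- setdiff(consumption$household_id, pd$household_id)
  if (length(missing_hh)) {
    stop("consumption records without a meal ledger: ",
         paste(head(missing_hh, 5), collapse = ", "), call. = FALSE)
  }
  out <- out[, c("household_id", "person_days", food_groups())]
  for (g in food_groups()) out[[g]] <- out[[g]] / out$person_days
  tibble::as_tibble(out)
}

intake_matrix <- function(intakes) {
  # accepts the wide tibble from standardize_intake(), a named vector, or
  # a bare numeric matrix with food-group columns
  if (is.data.frame(intakes)) {
    stopifnot(all(food_groups() %in% names(intakes)))
    m <- as.matrix(intakes[, food_groups()])
    rownames(m) <- if ("household_id" %in% names(intakes)) {
      as.character(intakes$household_id)
    } else NULL
    return(m)
  }
  if (is.matrix(intakes)) {
    stopifnot(all(food_groups() %in% colnames(intakes)))
    return(intakes[, food_groups(), drop = FALSE])
  }
  stopifnot(is.numeric(intakes), all(food_groups() %in% names(intakes)))
  matrix(intakes[food_groups()], nrow = 1,
         dimnames = list(NULL, food_groups()))
}

#' Entropy index of dietary diversity
#'
#' Shannon entropy of edible-weight shares across the twelve food groups:
#' `EI = -sum(w_i * log(w_i))` with `w_i` the proportion of total edible
#' weight contributed by group `i` and the convention `0 * log(0) = 0`.
#' The index runs from 0 (a single group) to `log(12) = 2.48` (perfectly
#' even intake); it is invariant to rescaling all weights.
#'
#' @param intakes Named numeric vector over [food_groups()], a matrix with
#'   those columns, or the wide tibble from [standardize_intake()]
#'   (grams/person/day; any common scale works).
#' @return Numeric vector of entropies in nats, one per household/row. A
#'   single household with zero total intake is an error; in matrix/tibble
#'   input zero-total rows are returned as `NA` with a warning so the
#'   caller can flag them (they are never silently scored 0).
#' @export
#' @examples
#' entropy_index(setNames(rep(100, 12), food_groups()))  # log(12)
entropy_index <- function(intakes) {
  m <- intake_matrix(intakes)
  if (any(m < 0)) stop("intakes must be non-negative.", call. = FALSE)
  tot <- rowSums(m)
  if (nrow(m) == 1L && tot <= 0) {
    stop("total intake is zero; the entropy index is undefined.",
         call. = FALSE)
  }
  w <- m / tot
  h <- -rowSums(ifelse(w > 0, w * log(w), 0))
  h[tot <= 0] <- NA_real_
  if (anyNA(h)) {
    warning("entropy index undefined (zero total intake) for ",
            sum(is.na(h)), " household(s); returned NA.", call. = FALSE)
  }
  unname(h)
}

#' Three-tier Pagoda category score
#'
#' Scores one Pagoda category's intake against its recommended band
#' `[L, U]`: 1 point inside the band, 0.5 if outside the band but within
#' 50% relative distance of either bound (`|intake - L| <= 0.5 L` or
#' `|intake - U| <= 0.5 U`), 0 otherwise. The full-credit band takes
#' precedence where the clauses overlap.
#'
#' @param intake Category intake, grams/person/day (vectorized).
#' @param L,U Lower and upper bounds, `0 < L <= U` (recycled).
#' @return Numeric vector of scores in `{0, 0.5, 1}`.
#' @export
#' @examples
#' pagoda_category_score(c(250, 560, 0), L = 250, U = 400)
pagoda_category_score <- function(intake, L, U) {
  if (any(!(L > 0 & L <= U))) {
    stop("Pagoda bounds must satisfy 0 < L <= U.", call. = FALSE)
  }
  if (any(intake < 0)) stop("intake must be non-negative.", call. = FALSE)
  in_band <- intake >= L & intake <= U
  near <- abs(intake - L) <= 0.5 * L | abs(intake - U) <= 0.5 * U
  ifelse(in_band, 1, ifelse(near, 0.5, 0))
}

category_intake_matrix <- function(intakes, mapping = default_pagoda_mapping()) {
  check_pagoda_mapping(mapping)
  m <- intake_matrix(intakes)
  agg <- sapply(pagoda_categories(), function(cat) {
    rowSums(m[, names(mapping)[mapping == cat], drop = FALSE])
  })
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1,
                                       dimnames = list(NULL, pagoda_categories()))
  agg
}

#' Aggregate category intakes for Pagoda scoring and SUR outcomes
#'
#' Sums per-capita food-group intakes into the eight Pagoda categories via
#' the group-to-category mapping.
#'
#' @inheritParams entropy_index
#' @param mapping Named character vector mapping food groups to
#'   categories; see [default_pagoda_mapping()].
#' @return Tibble with `household_id` (when available) and one column per
#'   Pagoda category (grams/person/day).
#' @export
category_intakes <- function(intakes, mapping = default_pagoda_mapping()) {
  agg <- category_intake_matrix(intakes, mapping)
  out <- tibble::as_tibble(agg)
  if (is.data.frame(intakes) && "household_id" %in% names(intakes)) {
    out <- dplyr::bind_cols(
      tibble::tibble(household_id = intakes$household_id), out)
  }
  out
}

#' Chinese Food Pagoda Score (0-8)
#'
#' Sum of the eight three-tier category scores after aggregating the
#' twelve food groups into Pagoda categories; rises as consumption
#' converges on the guideline ranges.
#'
#' @inheritParams category_intakes
#' @param bounds Bounds table as from [default_pagoda_bounds()].
#' @return Numeric vector of scores in `{0, 0.5, ..., 8}`.
#' @export
cfps <- function(intakes, mapping = default_pagoda_mapping(),
                 bounds = default_pagoda_bounds()) {
  check_pagoda_bounds(bounds)
  agg <- category_intake_matrix(intakes, mapping)
  b <- bounds[match(pagoda_categories(), bounds$category), ]
  s <- vapply(seq_along(pagoda_categories()), function(j) {
    pagoda_category_score(agg[, j], b$L[j], b$U[j])
  }, numeric(nrow(agg)))
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  unname(rowSums(s))
}

#' Single healthy-eating-index component score (0-5)
#'
#' Adequacy components (encouraged foods) score
#' `min(intake / R, 1) * 5`; limitation components (foods to curb) score 5
#' up to the ideal limit `L`, ramp linearly down to 0 at the cut-off `U`,
#' and 0 beyond. Both rules are continuous in intake; adequacy is
#' non-decreasing and limitation non-increasing.
#'
#' @param intake Intake in grams/person/day (vectorized).
#' @param kind `"adequacy"` or `"limitation"`.
#' @param R Recommended intake (adequacy components).
#' @param L,U Ideal upper limit and zero-point cut-off (limitation
#'   components), `0 <= L < U`.
#' @return Numeric vector of component scores in `[0, 5]`.
#' @export
#' @examples
#' chei_component_score(c(0, 125, 250, 500), "adequacy", R = 250)
#' chei_component_score(c(10, 30, 50), "limitation", L = 20, U = 40)
chei_component_score <- function(intake, kind, R = NA, L = NA, U = NA) {
  kind <- match.arg(kind, c("adequacy", "limitation"))
  if (any(intake < 0)) stop("intake must be non-negative.", call. = FALSE)
  if (kind == "adequacy") {
    if (is.na(R) || R <= 0) stop("adequacy needs R > 0.", call. = FALSE)
    return(pmin(intake / R, 1) * 5)
  }
  if (is.na(L) || is.na(U) || !(L >= 0 && L < U)) {
    stop("limitation needs 0 <= L < U.", call. = FALSE)
  }
  pmax(0, pmin(1, 1 - (intake - L) / (U - L))) * 5
}

#' Chinese Healthy Eating Index, 0-60 equal-weight variant
#'
#' Sums the twelve 5-point component scores (one per food group). Higher
#' values mean the diet is simultaneously nutrient-dense (adequacy
#' components near their recommended intakes) and restrained in foods to
#' curb (limitation components below their ideal limits).
#'
#' @inheritParams entropy_index
#' @param components Component table as from [default_chei_components()].
#' @return Numeric vector of scores in `[0, 60]`.
#' @export
chei <- function(intakes, components = default_chei_components()) {
  check_chei_components(components)
  m <- intake_matrix(intakes)
  comp <- components[match(food_groups(), components$component), ]
  s <- vapply(seq_along(food_groups()), function(k) {
    chei_component_score(m[, k], comp$kind[k], comp$R[k], comp$L[k],
                         comp$U[k])
  }, numeric(nrow(m)))
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  unname(rowSums(s))
}

#' Score a whole survey: EI, CFPS and CHEI per household
#'
#' Batch driver: standardizes intake with the meal ledger, then computes
#' the three indices for every household. Households whose scores are
#' undefined (zero total person-meals or zero total intake) are excluded
#' with a reason code rather than scored 0 — the indices are undefined
#' there, and regression samples should drop such rows explicitly.
#'
#' @inheritParams standardize_intake
#' @inheritParams cfps
#' @inheritParams chei
#' @return Tibble with columns `household_id`, `person_days`, `EI`,
#'   `CFPS`, `CHEI`. Excluded households are recorded in the `"dropped"`
#'   attribute (a tibble of `household_id`, `reason`) and reported via a
#'   warning.
#' @export
score_dataset <- function(consumption, meals,
                          mapping = default_pagoda_mapping(),
                          bounds = default_pagoda_bounds(),
                          components = default_chei_components(),
                          meals_per_day = 3) {
  if (nrow(consumption) == 0L) {
    warning("no consumption records; returning empty score table.",
            call. = FALSE)
    out <- tibble::tibble(household_id = character(), person_days = numeric(),
                          EI = numeric(), CFPS = numeric(), CHEI = numeric())
    attr(out, "dropped") <- tibble::tibble(household_id = character(),
                                           reason = character())
    return(out)
  }
  extra <- setdiff(unique(consumption$household_id),
                   unique(meals$household_id))
  if (length(extra)) {
    stop("household id(s) present in consumption but not in the meal ",
         "ledger: ", paste(head(extra, 5), collapse = ", "), call. = FALSE)
  }

  pm <- meals |>
    dplyr::group_by(.data$household_id) |>
    dplyr::summarise(total = sum(.data$family_person_meals +
                                   .data$guest_person_meals),
                     .groups = "drop")
  no_meals <- pm$household_id[pm$total <= 0]
  keep_meals <- meals[!meals$household_id %in% no_meals, , drop = FALSE]
  keep_cons <- consumption[!consumption$household_id %in% no_meals, ,
                           drop = FALSE]

  intakes <- standardize_intake(keep_cons, keep_meals, meals_per_day)
  tot <- rowSums(intake_matrix(intakes))
  no_intake <- intakes$household_id[tot <= 0]
  scored <- intakes[tot > 0, , drop = FALSE]

  out <- tibble::tibble(
    household_id = scored$household_id,
    person_days = scored$person_days,
    EI = entropy_index(scored),
    CFPS = cfps(scored, mapping, bounds),
    CHEI = chei(scored, components)
  )
  dropped <- dplyr::bind_rows(
    tibble::tibble(household_id = as.character(no_meals),
                   reason = "zero_person_meals"),
    tibble::tibble(household_id = as.character(no_intake),
                   reason = "zero_total_intake")
  )
  if (nrow(dropped)) {
    warning(nrow(dropped), " household(s) excluded from scoring (",
            paste(unique(dropped$reason), collapse = ", "), ").",
            call. = FALSE)
  }
  attr(out, "dropped") <- dropped
  out
}
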