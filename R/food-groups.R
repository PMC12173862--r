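#' The twelve food groups used throughout the package
#'
#' Canonical food-group vocabulary for 3-day household food-consumption
#' records. Sugar, sweets and soft drinks are deliberately excluded: they
#' add apparent diversity without improving diet quality, so all three
#' indices are computed over these twelve groups only.
#'
#' @return Character vector of length 12 in canonical order.
#' @export
#' @examples
#' food_groups()
food_groups <- function() {
  c("cereals", "tubers", "dried_legumes", "vegetables", "fungi_algae",
    "fruits", "nuts_seeds", "meat", "poultry", "dairy", "eggs", "aquatic")
}

#' The eight Chinese Dietary Pagoda categories
#'
#' The 2016 Chinese Dietary Pagoda states recommended daily intake ranges
#' for eight core categories. The twelve food groups are aggregated into
#' these categories before Pagoda adherence scoring.
#'
#' @return Character vector of length 8 in canonical order.
#' @export
pagoda_categories <- function() {
  c("grains_tubers_legumes", "vegetables", "fruits", "meat_poultry",
    "eggs", "aquatic", "dairy", "nuts_seeds")
}

#' Default mapping from food groups to Pagoda categories
#'
#' Cereals, tubers and dried legumes fold into the grains/tubers/legumes
#' category; fungi/algae are counted with vegetables; meat and poultry
#' merge into one category. The mapping is a named character vector and can
#' be replaced wholesale wherever a `mapping` argument is accepted, as long
#' as it stays total over [food_groups()] and onto [pagoda_categories()].
#'
#' @return Named character vector: names are food groups, values are
#'   Pagoda categories.
#' @export
#' @examples
#' default_pagoda_mapping()
default_pagoda_mapping <- function() {
  c(cereals       = "grains_tubers_legumes",
    tubers        = "grains_tubers_legumes",
    dried_legumes = "grains_tubers_legumes",
    vegetables    = "vegetables",
    fungi_algae   = "vegetables",
    fruits        = "fruits",
    nuts_seeds    = "nuts_seeds",
    meat          = "meat_poultry",
    poultry       = "meat_poultry",
    dairy         = "dairy",
    eggs          = "eggs",
    aquatic       = "aquatic")
}

check_pagoda_mapping <- function(mapping) {
  if (!setequal(names(mapping), food_groups())) {
    stop("`mapping` must be named by exactly the 12 food groups.",
         call. = FALSE)
  }
  if (!all(mapping %in% pagoda_categories())) {
    stop("`mapping` values must be Pagoda categories.", call. = FALSE)
  }
  if (!setequal(unique(mapping), pagoda_categories())) {
    stop("every Pagoda category needs at least one source food group.",
         call. = FALSE)
  }
  invisible(mapping)
}

#' Default Pagoda intake bounds
#'
#' Lower and upper recommended daily intakes (grams/person/day) per Pagoda
#' category, seeded from the 2016 Chinese Dietary Pagoda ranges. These are
#' editable defaults shipped as a plain CSV
#' (`system.file("extdata", "pagoda_bounds.csv", package = "ruraldiet")`);
#' every scoring rule depends only on the three-tier structure, not on the
#' particular numbers.
#'
#' @param path Optional path to a CSV with columns `category, L, U`.
#' @return Tibble with columns `category`, `L`, `U`.
#' @export
default_pagoda_bounds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pagoda_bounds.csv", package = "ruraldiet")
  }
  bounds <- readr::read_csv(path, col_types = readr::cols(
    category = readr::col_character(),
    L = readr::col_double(),
    U = readr::col_double()
  ))
  check_pagoda_bounds(bounds)
  bounds
}

check_pagoda_bounds <- function(bounds) {
  stopifnot(all(c("category", "L", "U") %in% names(bounds)))
  if (!setequal(bounds$category, pagoda_categories()) ||
      nrow(bounds) != 8L) {
    stop("bounds table must have one row per Pagoda category.",
         call. = FALSE)
  }
  if (any(!(bounds$L > 0 & bounds$L <= bounds$U))) {
    stop("Pagoda bounds must satisfy 0 < L <= U.", call. = FALSE)
  }
  invisible(bounds)
}

#' Default healthy-eating-index component table
#'
#' One scoring component per food group, each worth 5 points, so the index
#' runs 0-60. A component is either an adequacy component (encouraged food,
#' scored `min(intake/R, 1) * 5`) or a limitation component (food to curb,
#' scored by a descending ramp between `L` and `U`). The default table
#' classifies all twelve groups as adequacy components with recommended
#' intakes seeded from the 2016 Pagoda mid-ranges; limitation components
#' can be declared by editing the CSV
#' (`system.file("extdata", "chei_components.csv", package = "ruraldiet")`).
#'
#' @param path Optional path to a CSV with columns
#'   `component, kind, R, L, U`.
#' @return Tibble with columns `component`, `kind`, `R`, `L`, `U`.
#' @export
default_chei_components <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chei_components.csv",
                        package = "ruraldiet")
  }
  comp <- readr::read_csv(path, col_types = readr::cols(
    component = readr::col_character(),
    kind = readr::col_character(),
    R = readr::col_double(),
    L = readr::col_double(),
    U = readr::col_double()
  ))
  check_chei_components(comp)
  comp
}

check_chei_components <- function(comp) {
  stopifnot(all(c("component", "kind", "R", "L", "U") %in% names(comp)))
  if (!setequal(comp$component, food_groups()) || nrow(comp) != 12L) {
    stop("component table must have one row per food group (12 rows).",
         call. = FALSE)
  }
  if (!all(comp$kind %in% c("adequacy", "limitation"))) {
    stop("component `kind` must be 'adequacy' or 'limitation'.",
         call. = FALSE)
  }
  adeq <- comp$kind == "adequacy"
  if (any(adeq & !(comp$R > 0), na.rm = TRUE) || any(adeq & is.na(comp$R))) {
    stop("adequacy components need R > 0.", call. = FALSE)
  }
  lim <- !adeq
  bad_lim <- lim & (is.na(comp$L) | is.na(comp$U) |
                      !(comp$L >= 0 & comp$L < comp$U))
  if (any(bad_lim)) {
    stop("limitation components need 0 <= L < U.", call. = FALSE)
  }
  invisible(comp)
}

#' Score a dietary-knowledge battery
#'
#' The dietary knowledge index (DKI) counts correct answers to a 9-item
#' diet-knowledge battery (items drawn from the China Health and Nutrition
#' Survey style of questions); incorrect and "unknown" answers score 0, so
#' the index runs 0-9.
#'
#' @param correct Logical vector of length 9: was each item answered
#'   correctly? `NA` (unknown) counts as incorrect.
#' @return Integer score in 0..9.
#' @export
#' @examples
#' dki_score(c(TRUE, TRUE, FALSE, TRUE, NA, TRUE, TRUE, FALSE, TRUE))
dki_score <- function(correct) {
  if (length(correct) != 9L || !is.logical(correct)) {
    stop("`correct` must be a logical vector of length 9.", call. = FALSE)
  }
  sum(correct, na.rm = TRUE)
}
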