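test_that("meal-ledger standardization divides by at-home person-days", {
  cons <- tibble::tibble(household_id = "h1", day = 1,
                         food_group = "vegetables", grams = 9000)
  ml <- tibble::tibble(household_id = "h1", day = 1:3,
                       family_person_meals = 9, guest_person_meals = 0)
  out <- standardize_intake(cons, ml)  # 27 person-meals -> 9 person-days
  expect_equal(out$person_days, 9)
  expect_equal(out$vegetables, 1000)
  expect_equal(out$cereals, 0)  # absent groups are zero

  ml$guest_person_meals <- 3   # 9 guest person-meals -> 12 person-days
  out2 <- standardize_intake(cons, ml)
  expect_equal(out2$vegetables, 750)

  ml0 <- tibble::tibble(household_id = "h1", day = 1:3,
                        family_person_meals = 0, guest_person_meals = 0)
  expect_error(standardize_intake(cons, ml0), "zero total person-meals")
  expect_error(
    standardize_intake(dplyr::mutate(cons, grams = -1), ml),
    "negative grams")
  expect_error(
    standardize_intake(dplyr::mutate(cons, food_group = "sweets"), ml),
    "unknown food group")
})

test_that("duplicate household-day-group rows are summed before scoring", {
  cons <- tibble::tibble(household_id = "h1", day = c(1, 1, 2),
                         food_group = "fruits", grams = c(100, 200, 300))
  ml <- tibble::tibble(household_id = "h1", day = 1:3,
                       family_person_meals = 3, guest_person_meals = 0)
  out <- standardize_intake(cons, ml)
  expect_equal(out$fruits, 600 / 3)
})

test_that("entropy index matches the closed form on uniform intakes", {
  expect_equal(entropy_index(make_intake(setNames(rep(5, 12),
                                                  food_groups()))),
               log(12))
  expect_equal(round(log(12), 2), 2.48)
  expect_equal(entropy_index(make_intake(cereals = 123)), 0)
  expect_equal(entropy_index(make_intake(cereals = 1, fruits = 1)), log(2))
  # uniform over exactly k groups -> log(k), k = 2..12
  for (k in 2:12) {
    v <- make_intake(setNames(rep(7, k), food_groups()[seq_len(k)]))
    expect_equal(entropy_index(v), log(k))
  }
})

test_that("entropy index is scale invariant and bounded", {
  set.seed(4)
  for (i in 1:25) {
    v <- make_intake(setNames(rgamma(12, 1), food_groups()))
    h <- entropy_index(v)
    expect_gte(h, 0); expect_lte(h, log(12))
    expect_equal(entropy_index(v * 10), h)
    expect_equal(entropy_index(v * 0.037), h)
  }
})

test_that("zero total intake is flagged, never silently scored zero", {
  expect_error(entropy_index(make_intake()), "undefined")
  m <- rbind(make_intake(cereals = 10), make_intake())
  expect_warning(h <- entropy_index(m), "zero total intake")
  expect_equal(h, c(0, NA))
})

test_that("the three-tier Pagoda rule scores bands and near-bands", {
  L <- 250; U <- 400
  expect_equal(pagoda_category_score(L, L, U), 1)        # exactly at L
  expect_equal(pagoda_category_score(U, L, U), 1)
  expect_equal(pagoda_category_score(1.4 * U, L, U), 0.5)
  expect_equal(pagoda_category_score(0, L, U), 0)
  expect_equal(pagoda_category_score(0.4 * L, L, U), 0)
  expect_equal(pagoda_category_score(0.5 * L, L, U), 0.5)
  expect_error(pagoda_category_score(10, 0, 5), "0 < L <= U")
  expect_error(pagoda_category_score(10, 6, 5), "0 < L <= U")
  set.seed(8)
  s <- pagoda_category_score(runif(500, 0, 1000), 250, 400)
  expect_true(all(s %in% c(0, 0.5, 1)))
})

test_that("the Pagoda score sums to 8 in-band and steps by halves", {
  b <- default_pagoda_bounds()
  mapping <- default_pagoda_mapping()
  # put the whole category intake on one source group per category
  rep_group <- vapply(pagoda_categories(), function(cat) {
    names(mapping)[mapping == cat][1]
  }, character(1))
  mid <- setNames((b$L + b$U) / 2, b$category)
  in_band <- make_intake(setNames(mid[pagoda_categories()],
                                  rep_group[pagoda_categories()]))
  expect_equal(cfps(in_band), 8)
  expect_equal(cfps(make_intake()), 0)

  one_off <- in_band
  u_egg <- b$U[b$category == "eggs"]
  one_off[rep_group[["eggs"]]] <- 1.4 * u_egg
  expect_equal(cfps(one_off), 7.5)
})

test_that("moving an out-of-band category toward its band never lowers CFPS", {
  b <- default_pagoda_bounds()
  mapping <- default_pagoda_mapping()
  rep_group <- vapply(pagoda_categories(), function(cat) {
    names(mapping)[mapping == cat][1]
  }, character(1))
  set.seed(15)
  for (i in 1:40) {
    intake <- make_intake(setNames(runif(8, 0, 1200), rep_group))
    cat_j <- sample(pagoda_categories(), 1)
    L <- b$L[b$category == cat_j]; U <- b$U[b$category == cat_j]
    g <- rep_group[[cat_j]]
    x <- intake[[g]]
    if (x >= L && x <= U) next
    target <- if (x < L) L else U
    moved <- intake
    moved[[g]] <- x + 0.5 * (target - x)   # halfway toward the band
    expect_gte(cfps(moved), cfps(intake))
  }
})

test_that("adequacy and limitation component rules are exact", {
  expect_equal(chei_component_score(250, "adequacy", R = 250), 5)
  expect_equal(chei_component_score(500, "adequacy", R = 250), 5)
  expect_equal(chei_component_score(125, "adequacy", R = 250), 2.5)
  expect_equal(chei_component_score(30, "limitation", L = 20, U = 40), 2.5)
  expect_equal(chei_component_score(45, "limitation", L = 20, U = 40), 0)
  expect_equal(chei_component_score(40, "limitation", L = 20, U = 40), 0)
  expect_equal(chei_component_score(20, "limitation", L = 20, U = 40), 5)
  expect_equal(chei_component_score(5, "limitation", L = 20, U = 40), 5)
  expect_error(chei_component_score(1, "adequacy", R = 0), "R > 0")
  expect_error(chei_component_score(1, "limitation", L = 5, U = 5),
               "0 <= L < U")
})

test_that("component scores are continuous and monotone in intake", {
  grid <- seq(0, 100, by = 0.5)
  adeq <- chei_component_score(grid, "adequacy", R = 60)
  lim <- chei_component_score(grid, "limitation", L = 30, U = 70)
  expect_true(all(diff(adeq) >= 0))
  expect_true(all(diff(lim) <= 0))
  expect_true(all(abs(diff(adeq)) < 0.1 & abs(diff(lim)) < 0.1))
  expect_true(all(adeq >= 0 & adeq <= 5 & lim >= 0 & lim <= 5))
})

test_that("the healthy-eating index attains 0, 30 and 60 where expected", {
  comp <- default_chei_components()
  at_target <- make_intake(setNames(
    comp$R[match(food_groups(), comp$component)], food_groups()))
  expect_equal(chei(at_target), 60)
  expect_equal(chei(make_intake(cereals = 1e-9)), 0, tolerance = 1e-6)

  # six groups at full credit, six at zero
  half <- make_intake(setNames(
    comp$R[match(food_groups()[1:6], comp$component)], food_groups()[1:6]))
  expect_equal(chei(half), 30)

  # with limitation components, the maximum is met at/below the limit
  comp2 <- comp
  lim_rows <- comp2$component %in% c("meat", "aquatic")
  comp2$kind[lim_rows] <- "limitation"
  comp2$R[lim_rows] <- NA
  comp2$L[lim_rows] <- 50; comp2$U[lim_rows] <- 150
  ideal <- at_target
  ideal[c("meat", "aquatic")] <- c(50, 0)
  expect_equal(chei(ideal, comp2), 60)
  over <- ideal; over["meat"] <- 200
  expect_equal(chei(over, comp2), 55)
})

test_that("vectorized batch scoring equals scalar recomputation", {
  set.seed(44)
  n <- 1000
  m <- matrix(rgamma(n * 12, shape = 0.6, scale = 120), nrow = n,
              dimnames = list(NULL, food_groups()))
  # wrap the matrix into consumption records + a ledger with 9 person-days
  cons <- tibble::tibble(
    household_id = rep(sprintf("h%04d", 1:n), each = 12),
    day = 1L,
    food_group = rep(food_groups(), n),
    grams = as.vector(t(m)) * 9
  )
  ml <- tibble::tibble(household_id = rep(sprintf("h%04d", 1:n), 3),
                       day = rep(1:3, each = n),
                       family_person_meals = 9, guest_person_meals = 0)
  batch <- score_dataset(cons, ml)
  expect_equal(nrow(batch), n)
  idx <- sample(n, 60)  # scalar oracle on a subsample
  for (i in idx) {
    v <- setNames(m[i, ], food_groups())
    hid <- sprintf("h%04d", i)
    row <- batch[batch$household_id == hid, ]
    expect_equal(row$EI, entropy_index(v))
    expect_equal(row$CFPS, cfps(v))
    expect_equal(row$CHEI, chei(v))
  }
})

test_that("batch scoring drops undefined households with reason codes", {
  cons <- tibble::tibble(
    household_id = c("h1", "h2", "h3"), day = 1,
    food_group = "vegetables", grams = c(900, 0, 500))
  ml <- tibble::tibble(
    household_id = rep(c("h1", "h2", "h3", "h4"), each = 3),
    day = rep(1:3, 4),
    family_person_meals = c(rep(9, 6), rep(0, 3), rep(9, 3)),
    guest_person_meals = 0)
  expect_warning(sc <- score_dataset(cons, ml), "excluded")
  expect_equal(sc$household_id, "h1")
  dropped <- attr(sc, "dropped")
  expect_setequal(dropped$reason[dropped$household_id == "h3"],
                  "zero_person_meals")
  expect_setequal(dropped$reason[dropped$household_id == "h2"],
                  "zero_total_intake")

  expect_error(score_dataset(dplyr::mutate(cons, household_id = "h9"),
                             ml), "not in the meal ledger")
  expect_warning(empty <- score_dataset(cons[0, ], ml), "no consumption")
  expect_equal(nrow(empty), 0)
})
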