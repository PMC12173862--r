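small_spec <- function() {
  regression_spec("y", focal = c("x1", "x2"), controls = character(),
                  fe = "county_id", cluster = "household_id")
}

test_that("cluster-robust SEs match the hand-coded sandwich oracle", {
  df <- small_reg_fixture()
  fit <- fit_main_model(df, small_spec())
  X <- model.matrix(fit$model)
  e <- resid(fit$model)
  V <- hand_cluster_vcov(X, e, df$household_id)  # singleton clusters
  expect_lt(max(abs(fit$vcov - V) / abs(V)), 1e-10)

  # true clusters: same oracle with the county as the cluster factor
  spec_c <- small_spec(); spec_c$cluster <- "county_id"
  fit_c <- fit_main_model(df, spec_c)
  Vc <- hand_cluster_vcov(model.matrix(fit_c$model), resid(fit_c$model),
                          df$county_id)
  expect_lt(max(abs(fit_c$vcov - Vc) / abs(Vc)), 1e-10)
})

test_that("singleton clusters reduce to heteroskedasticity-robust SEs", {
  df <- small_reg_fixture(seed = 23)
  fit <- fit_main_model(df, small_spec())
  n <- fit$n; k <- length(coef(fit$model))
  X <- model.matrix(fit$model); e <- resid(fit$model)
  hc1 <- n / (n - k) * solve(crossprod(X)) %*% crossprod(X * e) %*%
    solve(crossprod(X))
  expect_equal(unname(fit$vcov), unname(hc1), tolerance = 1e-12)
})

test_that("collinear regressors error, or drop on request", {
  df <- small_reg_fixture()
  df$x_dup <- df$x1
  spec <- regression_spec("y", focal = c("x1", "x2", "x_dup"),
                          controls = character(), fe = "county_id")
  expect_error(fit_main_model(df, spec), "collinear")
  expect_warning(fit2 <- fit_main_model(df, spec, on_collinear = "drop"),
                 "dropping")
  expect_false("x_dup" %in% coef_table(fit2)$term)
})

test_that("a county-constant column is absorbed by the fixed effects", {
  df <- small_reg_fixture(seed = 31)
  base <- fit_main_model(df, small_spec())
  df$county_level <- ifelse(df$county_id == "a", 1.7, -0.4)
  spec2 <- regression_spec("y", focal = c("x1", "x2"),
                           controls = "county_level", fe = "county_id")
  expect_warning(fit2 <- fit_main_model(df, spec2, on_collinear = "drop"))
  for (tm in c("x1", "x2")) {
    expect_equal(coef_table(fit2)$estimate[coef_table(fit2)$term == tm],
                 coef_table(base)$estimate[coef_table(base)$term == tm],
                 tolerance = 1e-8)
  }
})

test_that("rows with missing fields are dropped listwise and counted", {
  df <- small_reg_fixture()
  df$x1[c(2, 5)] <- NA
  fit <- fit_main_model(df, small_spec())
  expect_equal(fit$n, 18)
  expect_equal(fit$n_dropped, 2)
})

test_that("median and custom splits partition the sample as configured", {
  set.seed(61)
  n <- 100
  df <- tibble::tibble(
    y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
    income = runif(n),
    county_id = rep(c("a", "b"), n / 2),
    household_id = sprintf("h%03d", 1:n))
  spec <- small_spec()
  het <- run_heterogeneity(df, spec, "income", cut = "median")
  expect_equal(vapply(het$fits, function(f) f$n, numeric(1)),
               c(Low = 50, High = 50))

  # unequal custom strata in published-split proportions (575/310/194)
  n2 <- 1079
  df2 <- tibble::tibble(
    y = rnorm(n2), x1 = rnorm(n2), x2 = rnorm(n2),
    income = seq_len(n2) / 100,
    county_id = rep(c("a", "b"), length.out = n2),
    household_id = sprintf("h%04d", 1:n2))
  het2 <- run_heterogeneity(df2, spec, "income", cut = "custom",
                            thresholds = c(5.75, 8.85))
  expect_equal(unname(vapply(het2$fits, function(f) f$n, numeric(1))),
               c(575, 310, 194))

  expect_error(run_heterogeneity(df, spec, "income", cut = "median",
                                 min_n = 60), "below the minimum")
  expect_error(run_heterogeneity(df, spec, "nope"), "not in data")
})

test_that("income terciles omit income from the stratum regressions", {
  set.seed(62)
  n <- 240
  df <- tibble::tibble(
    y = rnorm(n), x1 = rnorm(n), income = rlnorm(n),
    county_id = rep(c("a", "b"), n / 2),
    household_id = sprintf("h%03d", 1:n))
  spec <- regression_spec("y", focal = c("x1", "income"),
                          controls = character(), fe = "county_id")
  het <- run_heterogeneity(df, spec, "income", cut = "tercile")
  expect_equal(length(het$fits), 3L)
  expect_false("income" %in% het$table$term)
  # median split keeps income as a regressor
  het_m <- run_heterogeneity(df, spec, "income", cut = "median")
  expect_true("income" %in% het_m$table$term)
})

test_that("stratum fits recover a planted interaction", {
  set.seed(63)
  n <- 1200
  low <- rep(c(TRUE, FALSE), each = n / 2)
  df <- tibble::tibble(
    elderly = runif(n, 0, 100),
    income = ifelse(low, runif(n, 0, 1), runif(n, 2, 3)),
    county_id = rep(c("a", "b"), n / 2),
    household_id = sprintf("h%04d", 1:n))
  # elderly effect -0.02 in the low-income half only
  df$y <- 1 + ifelse(low, -0.02, 0) * df$elderly + rnorm(n, 0, 0.3)
  spec <- regression_spec("y", focal = c("elderly", "income"),
                          controls = character(), fe = "county_id")
  het <- run_heterogeneity(df, spec, "income", cut = "median")
  tb <- het$table
  lo <- tb[tb$stratum == "Low" & tb$term == "elderly", ]
  hi <- tb[tb$stratum == "High" & tb$term == "elderly", ]
  expect_lt(lo$estimate, 0)
  expect_lt(lo$p, 0.05)
  expect_lt(abs(hi$estimate - 0), 3 * hi$se)
})

test_that("SUR with common regressors equals per-equation OLS", {
  set.seed(71)
  n <- 150
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  for (j in 1:4) df[[paste0("y", j)]] <- rnorm(n) + j * df$x1
  sur <- fit_sur(df, paste0("y", 1:4), c("x1", "x2"))
  for (j in 1:4) {
    ols <- coef(lm(df[[paste0("y", j)]] ~ df$x1 + df$x2))
    expect_equal(unname(sur$coefficients[, j]), unname(ols),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(sur$Sigma))
  expect_true(all(eigen(sur$Sigma, only.values = TRUE)$values > -1e-10))
})

test_that("the joint Wald statistic is invariant to equation order", {
  set.seed(72)
  n <- 200
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  for (j in 1:5) {
    df[[paste0("y", j)]] <- 0.3 * df$x1 + rnorm(n)
  }
  w1 <- fit_sur(df, paste0("y", 1:5), c("x1", "x2"), joint = "x1")$wald
  w2 <- fit_sur(df, paste0("y", c(3, 5, 1, 4, 2)), c("x1", "x2"),
                joint = "x1")$wald
  expect_equal(w1$wald, w2$wald, tolerance = 1e-10)
  expect_equal(w1$df, 5L)
})

test_that("SUR requires all outcomes on the same rows", {
  set.seed(73)
  df <- tibble::tibble(x1 = rnorm(30), y1 = rnorm(30), y2 = rnorm(30))
  df$y2[4] <- NA
  expect_error(fit_sur(df, c("y1", "y2"), "x1"), "same rows")
})

test_that("LASSO on a standardized single predictor soft-thresholds", {
  set.seed(81)
  n <- 300
  x <- rnorm(n); x <- x - mean(x); x <- x / sqrt(mean(x^2))
  y <- 0.8 * x + rnorm(n); y <- y - mean(y)
  df <- tibble::tibble(y = y, x = x, inert = 0)
  b_ols <- mean(x * y)
  grid <- sort(c(abs(b_ols) * c(2, 1), 0.3, 0.1, 0.02), decreasing = TRUE)
  fit <- fit_lasso_cv(df, "y", c("x", "inert"), nfolds = 5, seed = 2,
                      lambda = grid)
  for (i in seq_along(grid)) {
    expect_equal(unname(fit$beta_path["x", i]),
                 soft_threshold(b_ols, grid[i]), tolerance = 1e-6)
  }
  # above lambda_max every slope is exactly zero
  expect_equal(unname(fit$beta_path["x", 1]), 0)
})

test_that("the unpenalized end of the path equals OLS", {
  set.seed(82)
  n <- 250
  X <- scale(matrix(rnorm(n * 4), n))
  y <- X %*% c(1, -0.5, 0, 0.2) + rnorm(n)
  df <- tibble::as_tibble(as.data.frame(X))
  names(df) <- paste0("x", 1:4)
  df$y <- as.vector(y)
  fit <- fit_lasso_cv(df, "y", paste0("x", 1:4), nfolds = 5, seed = 3,
                      lambda = c(0.5, 0.1, 0.01, 0))
  ols <- coef(lm(y ~ ., data = df[, c("y", paste0("x", 1:4))]))
  at0 <- coef(fit$cvfit$glmnet.fit, s = 0, exact = FALSE)
  expect_equal(as.vector(at0), unname(ols), tolerance = 1e-4)
})

test_that("coefficients enter monotonically on an orthonormal design", {
  set.seed(83)
  n <- 400; p <- 5
  Q <- qr.Q(qr(matrix(rnorm(n * p), n))) * sqrt(n)  # X'X/n = I
  y <- Q %*% c(1, -0.6, 0.3, 0, 0) + rnorm(n)
  df <- tibble::as_tibble(as.data.frame(Q))
  names(df) <- paste0("x", 1:p); df$y <- as.vector(y)
  fit <- fit_lasso_cv(df, "y", paste0("x", 1:p), nfolds = 5, seed = 4)
  path <- abs(fit$beta_path)  # columns ordered by decreasing lambda
  for (j in 1:p) {
    expect_true(all(diff(path[j, ]) >= -1e-8))
  }
})

test_that("true predictors survive cross-validated selection", {
  set.seed(84)
  survived <- replicate(100, {
    n <- 300
    X <- matrix(rnorm(n * 10), n)
    colnames(X) <- c("ratio_over65", "income", paste0("z", 1:8))
    y <- -0.5 * X[, "ratio_over65"] + 0.6 * X[, "income"] + rnorm(n)
    df <- tibble::as_tibble(as.data.frame(X)); df$y <- y
    fit <- fit_lasso_cv(df, "y", colnames(X), nfolds = 10,
                        seed = sample.int(1e6, 1))
    all(c("ratio_over65", "income") %in% fit$survivors)
  })
  expect_gte(mean(survived), 0.90)
})

test_that("degenerate inputs are rejected", {
  df <- small_reg_fixture()
  expect_error(fit_lasso_cv(df[1:5, ], "y", c("x1", "x2"), nfolds = 10),
               "fewer rows than folds")
  expect_error(regression_spec("EI", focal = "income",
                               controls = c("income", "dki")),
               "both focal and control")
  expect_error(regression_spec("EI", controls = "ratio_18_65"),
               "reference category")
  expect_error(fit_main_model(df, regression_spec("nope",
                                                  focal = "x1",
                                                  controls = character())),
               "missing column")
})
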