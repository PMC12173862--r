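# Independent oracles and shared fixtures.

# a full named intake vector over the 12 food groups, zero by default
make_intake <- function(...) {
  v <- setNames(rep(0, 12), food_groups())
  args <- c(...)
  v[names(args)] <- args
  v
}

# hand-coded clustered sandwich covariance:
# adj * (X'X)^-1 (sum_g s_g s_g') (X'X)^-1, s_g = X_g' e_g,
# adj = G/(G-1) * (n-1)/(n-k)
hand_cluster_vcov <- function(X, e, cluster) {
  n <- nrow(X); k <- ncol(X)
  G <- length(unique(cluster))
  bread <- solve(crossprod(X))
  S <- vapply(unique(cluster), function(g) {
    colSums(X[cluster == g, , drop = FALSE] * e[cluster == g])
  }, numeric(k))
  meat <- tcrossprod(S)
  G / (G - 1) * (n - 1) / (n - k) * bread %*% meat %*% bread
}

soft_threshold <- function(b, lambda) sign(b) * pmax(abs(b) - lambda, 0)

# a small regression fixture with known structure: 20 rows, intercept +
# two regressors, one cluster per row
small_reg_fixture <- function(seed = 11) {
  set.seed(seed)
  n <- 20
  tibble::tibble(
    y = rnorm(n), x1 = rnorm(n), x2 = runif(n),
    county_id = rep(c("a", "b"), each = n / 2),
    household_id = sprintf("h%02d", seq_len(n))
  )
}

# Planted-effect recovery study, shared between the generator property
# test and the acceptance suite. Fits the EI and CHEI main models on
# fresh default-condition surveys and caches the focal coefficients.
.recovery_env <- new.env(parent = emptyenv())

recovery_study <- function(n_reps = 200, base_seed = 2000) {
  key <- sprintf("reps%d_seed%d", n_reps, base_seed)
  if (!is.null(.recovery_env[[key]])) return(.recovery_env[[key]])
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    svy <- generate_survey(seed = base_seed + i)
    sc <- suppressWarnings(score_dataset(svy$consumption, svy$meals))
    dat <- analysis_frame(sc, svy$covariates)
    per_index <- lapply(c("EI", "CHEI"), function(ix) {
      tb <- coef_table(fit_main_model(dat, regression_spec(ix)))
      tb <- tb[tb$term %in% c("ratio_over65", "income"), ]
      tb$index <- ix
      tb
    })
    rows[[i]] <- dplyr::bind_rows(per_index)
  }
  out <- dplyr::bind_rows(rows, .id = "rep")
  .recovery_env[[key]] <- out
  out
}

planted_value <- function(index, term) {
  spec <- default_effects()[[index]]
  switch(term, ratio_over65 = spec$beta_over65,
         income = spec$gamma_income,
         ratio_under18 = spec$beta_under18)
}
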