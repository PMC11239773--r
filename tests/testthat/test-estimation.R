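test_that("the model grid encodes the 16 analysis models correctly", {
  grid <- model_grid()
  expect_equal(nrow(grid), 16)
  expect_equal(sum(grid$level == "individual"), 6)
  expect_equal(sum(grid$level == "cluster"), 10)
  # race HTE requires race adjustment
  expect_true(all(grid$adjust_race[grid$hte_race]))
  # proportion vs indicator encodings alternate over the adjusted cluster models
  expect_equal(grid$race_encoding[grid$model_id %in% c("2c", "2e", "2g", "2i")],
               rep("proportion", 4))
  expect_equal(grid$race_encoding[grid$model_id %in% c("2d", "2f", "2h", "2j")],
               rep("indicator", 4))
  # the four race-HTE cluster models
  expect_equal(grid$model_id[grid$level == "cluster" & grid$hte_race],
               c("2g", "2h", "2i", "2j"))
  expect_error(model_spec("3a"), "unknown model")
})

test_that("design matrices have the documented columns, in order", {
  trial <- fixture_trial()
  dm <- build_design_matrix(trial$individuals, model_spec("1a"))
  expect_identical(colnames(dm$x),
                   c("(Intercept)", "arm", "urban", "region"))

  dm_2i <- build_design_matrix(trial$summary, model_spec("2i"))
  expect_identical(
    colnames(dm_2i$x),
    c("(Intercept)", "arm", "urban", "region", "race", "arm:urban", "arm:race")
  )
  # the race column is the centered proportion; interactions are products
  expect_equal(unname(dm_2i$x[, "race"]),
               trial$summary$race_proportion_centered)
  expect_equal(dm_2i$x[, "arm:urban"], dm_2i$x[, "arm"] * dm_2i$x[, "urban"])
  expect_equal(dm_2i$x[, "arm:race"], dm_2i$x[, "arm"] * dm_2i$x[, "race"])

  dm_2j <- build_design_matrix(trial$summary, model_spec("2j"))
  expect_equal(unname(dm_2j$x[, "race"]),
               as.numeric(trial$summary$race_indicator))

  # a constant requested column is flagged as degenerate
  ind0 <- trial$individuals
  ind0$race <- 0L
  dm_deg <- build_design_matrix(ind0, model_spec("1f"))
  expect_true(all(c("race", "arm:race") %in% dm_deg$degenerate_terms))
  fit_deg <- fit_hte_model(ind0, "1f")
  expect_true(fit_deg$degenerate)
  expect_equal(nrow(tidy(fit_deg)), 0)

  expect_error(
    build_design_matrix(trial$summary[, c("cluster_id", "mean_outcome")],
                        model_spec("2a")),
    "missing column"
  )
})

test_that("OLS estimates match the normal-equations oracle on every model", {
  trial <- simulate_trial(K = 20, n_staff = 30, scenario = 9, seed = 555)
  grid <- model_grid()
  for (id in grid$model_id) {
    spec <- model_spec(id)
    data <- if (spec$level == "individual") trial$individuals else trial$summary
    fit <- fit_hte_model(data, spec)
    if (fit$degenerate) next
    dm <- build_design_matrix(data, spec)
    expect_equal(fit$coefficients$estimate, unname(oracle_ols(dm$x, dm$y)),
                 tolerance = 1e-10, info = id)
  }
})

test_that("an exactly linear response is recovered without error", {
  trial <- simulate_trial(K = 10, n_staff = 10, scenario = 1, seed = 31)
  ind <- trial$individuals
  b <- c(0.2, 0.1, 0.05, -0.02)
  ind$outcome <- b[1] + b[2] * ind$arm + b[3] * ind$urban + b[4] * ind$region
  fit <- suppressWarnings(fit_hte_model(ind, "1a")) # perfect fit is the point
  expect_equal(fit$coefficients$estimate, b, tolerance = 1e-12)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
})

test_that("cluster sandwich covariance equals the double-loop oracle (K = 6 toy data)", {
  trial <- simulate_trial(K = 6, n_staff = 10, scenario = 9, seed = 66,
                          region_split = 0.5)
  dm <- build_design_matrix(trial$individuals, model_spec("1f"))
  fit <- lm(dm$y ~ dm$x - 1)
  V <- cluster_robust_vcov(fit, dm$cluster)
  V_oracle <- oracle_cluster_vcov(dm$x, unname(fit$residuals), dm$cluster)
  expect_equal(unname(V), unname(V_oracle), tolerance = 1e-12)

  # residuals all zero -> zero matrix
  y_exact <- dm$x %*% oracle_ols(dm$x, dm$y)
  fit0 <- lm(y_exact ~ dm$x - 1)
  expect_equal(
    suppressWarnings(unname(cluster_robust_vcov(fit0, dm$cluster))),
    matrix(0, ncol(dm$x), ncol(dm$x)),
    tolerance = 1e-20
  )

  # one observation per cluster reduces to the HC0 robust form
  trial12 <- simulate_trial(K = 12, n_staff = 15, scenario = 9, seed = 67)
  dm_c <- build_design_matrix(trial12$summary, model_spec("2i"))
  fit_c <- lm(dm_c$y ~ dm_c$x - 1)
  V_c <- cluster_robust_vcov(fit_c, dm_c$cluster)
  expect_equal(unname(V_c),
               unname(oracle_cluster_vcov(dm_c$x, unname(fit_c$residuals),
                                          seq_along(dm_c$y))),
               tolerance = 1e-12)
})

test_that("sandwich covariances are symmetric positive semi-definite", {
  for (s in 1:5) {
    trial <- simulate_trial(K = 12, n_staff = 15, scenario = 9, seed = 700 + s)
    for (id in c("1f", "2i", "2j")) {
      data <- if (model_spec(id)$level == "individual") {
        trial$individuals
      } else {
        trial$summary
      }
      fit <- fit_hte_model(data, id)
      if (fit$degenerate) next
      expect_equal(fit$vcov, t(fit$vcov))
      expect_gte(min(eigen(fit$vcov, symmetric = TRUE)$values), -1e-12)
    }
  }
})

test_that("the K/(K-2) correction scales the covariance entrywise", {
  V <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(small_sample_correction(V, 40), V * 40 / 38)
  expect_equal(small_sample_correction(V, 30), V * 30 / 28)
  expect_equal(small_sample_correction(V, 1e9), V, tolerance = 1e-8)
  expect_error(small_sample_correction(V, 2), "exceed 2")

  # the fit applies it on top of the uncorrected sandwich
  trial <- simulate_trial(K = 6, n_staff = 10, scenario = 9, seed = 66)
  dm <- build_design_matrix(trial$individuals, model_spec("1f"))
  fit_lm <- lm(dm$y ~ dm$x - 1)
  fit <- fit_hte_model(trial$individuals, "1f")
  expect_equal(unname(fit$vcov),
               unname(cluster_robust_vcov(fit_lm, dm$cluster)) * 6 / 4,
               tolerance = 1e-12)
})

test_that("Wald tests refer estimate/SE to the standard normal", {
  trial <- simulate_trial(K = 20, n_staff = 30, scenario = 6, seed = 888)
  fit <- fit_hte_model(trial$individuals, "1e")
  res <- wald_tests(fit, alpha = 0.05)
  # independent normal-CDF route
  expect_equal(res$p.value,
               2 * pnorm(-abs(res$estimate / res$std.error)))
  expect_identical(res$reject, res$p.value < 0.05)
  expect_true(all(res$std.error > 0))
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))

  # reference values: z = 0 -> p = 1; z = 1.96 -> p ~ 0.05
  expect_equal(2 * pnorm(-abs(0 / 1)), 1)
  expect_equal(2 * pnorm(-abs(1.96 / 1)), 0.05, tolerance = 1e-3)

  # optional t reference with K - 2 df is more conservative
  fit_t <- fit_hte_model(trial$individuals, "1e", df_method = "t")
  expect_true(all(fit_t$coefficients$p.value >= fit$coefficients$p.value))
})

test_that("tidy, glance and autoplot expose the fit", {
  trial <- fixture_trial()
  fit <- fit_hte_model(trial$individuals, "1c")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(gl$K, 4)
  expect_equal(gl$nobs, 20)
  expect_s3_class(autoplot(fit), "ggplot")
})
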