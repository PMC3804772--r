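published_coeffs <- lie_coefficients(0.072, -0.006, -0.951)

test_that("noiseless tables give exact coefficient recovery", {
  t1 <- load_fixture("table1")
  tab <- t1[, c("compound_id", "u_vdw", "u_elec", "u_cav")]
  tab$experimental_dg <- predict_dg(published_coeffs, tab)
  fit <- fit_lie(tab)
  expect_equal(unclass(fit$coefficients)[1:3],
               c(alpha = 0.072, beta = -0.006, gamma = -0.951),
               tolerance = 1e-10)
  expect_equal(unname(predict_dg(fit$coefficients, tab)),
               tab$experimental_dg, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("fit_lie matches the normal-equations oracle on random tables", {
  for (i in 1:20) {
    n <- sample(5:20, 1)
    cfg <- lie_sim_config(n_compounds = n, noise_sd = 0.1, seed = 100 + i)
    tab <- simulate_lie_table(cfg)
    for (intercept in c(FALSE, TRUE)) {
      fit <- fit_lie(tab, include_intercept = intercept)
      oracle <- oracle_lie_fit(tab, include_intercept = intercept)
      got <- unclass(fit$coefficients)[c("alpha", "beta", "gamma")]
      expect_equal(unname(got), unname(oracle$coefficients[1:3]),
                   tolerance = 1e-8)
      if (intercept) {
        expect_equal(fit$coefficients[["intercept"]],
                     unname(oracle$coefficients[["intercept"]]),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("coefficients are recovered within 3 standard errors under noise", {
  cfg <- lie_sim_config(
    coeffs_true = lie_coefficients(0.1, -0.01, -0.8),
    n_compounds = 50, noise_sd = 0.05, seed = 7
  )
  tab <- simulate_lie_table(cfg)
  fit <- fit_lie(tab)
  se <- oracle_lie_fit(tab)$se
  got <- unclass(fit$coefficients)[c("alpha", "beta", "gamma")]
  expect_true(all(abs(got - c(0.1, -0.01, -0.8)) <= 3 * se))
})

test_that("fit_lie rejects degenerate designs", {
  tab <- simulate_lie_table(lie_sim_config(n_compounds = 8, seed = 1))
  tab$u_elec <- 2 * tab$u_vdw  # exact collinearity
  expect_error(fit_lie(tab), "collinear")
  expect_error(fit_lie(tab[1:3, ]), "at least 4")
  tab2 <- simulate_lie_table(lie_sim_config(n_compounds = 8, seed = 1))
  tab2$compound_id[2] <- tab2$compound_id[1]
  expect_error(fit_lie(tab2), "unique")
})

test_that("predict_dg reproduces tabulated predicted free energies", {
  expect_equal(predict_dg(published_coeffs, c(-62.62, 76.07, 1.287)),
               -6.189, tolerance = 0.0005 / 6.189)
  expect_equal(predict_dg(published_coeffs, c(-57.50, 7.551, 0.776)),
               -4.923, tolerance = 0.0005 / 4.923)
  expect_equal(predict_dg(published_coeffs, c(0, 0, 0)), 0)

  # all 11 rows of the second compound table regenerate within print rounding
  t2 <- load_fixture("table2")
  pred <- predict_dg(published_coeffs, t2)
  expect_true(all(abs(pred - t2$predicted_dg) <= 0.002))
  expect_gte(sum(abs(pred - t2$predicted_dg) <= 0.0005), 10)
})

test_that("leave-one-out predictions behave as a cross-validation diagnostic", {
  # exact model: holding a row out changes nothing
  t1 <- load_fixture("table1")
  tab <- t1[, c("compound_id", "u_vdw", "u_elec", "u_cav")]
  tab$experimental_dg <- predict_dg(published_coeffs, tab)
  full <- predict_dg(fit_lie(tab)$coefficients, tab)
  expect_equal(loo_predictions(tab), full, tolerance = 1e-9)

  # a gross outlier is predicted worse out-of-fold than in-fold
  tab2 <- simulate_lie_table(lie_sim_config(n_compounds = 5, seed = 11))
  tab2$experimental_dg[3] <- tab2$experimental_dg[3] + 5
  fit <- fit_lie(tab2)
  loo <- loo_predictions(tab2)
  expect_gt(abs(tab2$experimental_dg[3] - loo[3]), abs(fit$residuals[3]))
})

test_that("squared correlation reproduces the published model statistics", {
  t1 <- load_fixture("table1")
  expect_equal(pearson_r2(t1$predicted_dg, t1$experimental_dg), 0.780,
               tolerance = 0.001 / 0.780)
  expect_equal(pearson_r2(t1$glide_xp_score, t1$experimental_dg), 0.615,
               tolerance = 0.001 / 0.615)
  t2 <- load_fixture("table2")
  meas <- !is.na(t2$kd_mean)
  expect_equal(pearson_r2(t2$predicted_dg[meas], t2$experimental_dg[meas]),
               0.675, tolerance = 0.001 / 0.675)
})

test_that("pearson_r2 is symmetric and affine-invariant", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  r2 <- pearson_r2(x, y)
  expect_equal(pearson_r2(y, x), r2)
  expect_equal(pearson_r2(-3 * x + 2, y), r2)
  expect_equal(pearson_r2(x, 0.1 * y - 7), r2)
  expect_equal(pearson_r2(x, 2 * x + 3), 1.0)
  expect_error(pearson_r2(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r2(1:2, 1:2), "at least 3")
})

test_that("summary-statistic ANOVA matches aov on reconstructed raw data", {
  means <- c(0, 1, 2.5); sds <- c(1, 1.4, 0.8); ns <- c(10, 12, 8)
  groups <- Map(group_with_moments, means, sds, ns, seed = 1:3)
  raw <- data.frame(y = unlist(groups),
                    g = factor(rep(seq_along(ns), ns)))
  ref <- summary(stats::aov(y ~ g, data = raw))[[1]]
  got <- anova_oneway_from_summary(means, sds, ns)
  expect_equal(got$F, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(got$df1, ref[["Df"]][1])
  expect_equal(got$df2, ref[["Df"]][2])
  expect_equal(got$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)

  # hand expansion for two simple groups: SSB = 5, SSW = 18, F = 5/1 * 18/18
  two <- anova_oneway_from_summary(c(0, 1), c(1, 1), c(10, 10))
  expect_equal(two$ss_between, 5)
  expect_equal(two$ss_within, 18)
  expect_equal(two$F, 5)

  equal_means <- anova_oneway_from_summary(c(3, 3), c(1, 2), c(5, 5))
  expect_equal(equal_means$F, 0)
  expect_error(anova_oneway_from_summary(c(1, 1), c(0, 0), c(3, 3)),
               "undefined")
})
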