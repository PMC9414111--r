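# Nested linear models: per-SD OLS, adjusted R-squared, nested F-tests,
# bootstrap R-squared intervals, VIF and residual diagnostics.

test_that("per-SD OLS matches an independent normal-equations oracle", {
  set.seed(51)
  for (r in 1:20) {
    n <- sample(15:30, 1); p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p, sd = runif(p, 0.5, 20)), n)
    colnames(X) <- paste0("x", seq_len(p))
    y <- rnorm(n, 3500, 400)
    dat <- tibble::tibble(as.data.frame(X), birthweight_adj = y)
    fit <- fit_bw_model(dat, colnames(X), binary = character())
    Z <- scale(X)  # oracle standardizes the same way (n-1 SD)
    orc <- normal_equations_fit(Z, y)
    expect_equal(unname(fit$coefficients$estimate), unname(orc$coef),
                 tolerance = 1e-8)
    expect_equal(fit$r2, orc$r2, tolerance = 1e-10)
    expect_equal(fit$rss, orc$rss, tolerance = 1e-8)
  }
})

test_that("perfect fits, intercept-only fits and rank deficiency behave as OLS dictates", {
  dat <- tibble::tibble(x = rnorm(30, 100, 10))
  dat$birthweight_adj <- 3000 + 5 * dat$x
  fit <- suppressWarnings(fit_bw_model(dat, "x", binary = character()))
  expect_equal(fit$r2, 1)
  expect_equal(unname(fit$coefficients$estimate[2]), 5 * sd(dat$x))

  f0 <- fit_bw_model(dat, character())
  expect_equal(f0$coefficients$estimate[1], mean(dat$birthweight_adj))
  expect_equal(f0$r2, 0)

  dat$x2 <- dat$x * 2
  expect_error(fit_bw_model(dat, c("x", "x2"), binary = character()),
               "rank deficient")
})

test_that("per-SD coefficients are invariant to the predictor's raw units", {
  set.seed(52)
  dat <- tibble::tibble(x = rnorm(80, 4, 0.5), z = rnorm(80))
  dat$birthweight_adj <- 3500 + 90 * scale(dat$x)[, 1] + rnorm(80, 0, 300)
  f1 <- fit_bw_model(dat, c("x", "z"), binary = character())
  dat$x <- dat$x * 18.016  # mmol/L -> mg/dL, say
  f2 <- fit_bw_model(dat, c("x", "z"), binary = character())
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(f1$coefficients$t, f2$coefficients$t, tolerance = 1e-10)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})

test_that("adjusted R-squared follows its definition and the emitted fits", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_error(adjusted_r2(0.5, 6, 5), "n > p")
  dat <- toy_analysis_table(120, seed = 3)
  f <- fit_bw_model(dat, bw_model_predictors("model2"))
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * (f$n - 1) /
                 (f$n - f$n_predictors - 1))
  expect_lte(f$adj_r2, f$r2)
  expect_gte(f$r2, 0)
})

test_that("nested F-test: identity forms, orthogonal-addition zero, and anova cross-check", {
  set.seed(53)
  n <- 60
  dat <- tibble::tibble(x1 = rnorm(n))
  dat$birthweight_adj <- 3500 + 80 * dat$x1 + rnorm(n, 0, 200)
  # orthogonalize a candidate against (1, x1, y): adding it cannot move RSS
  raw <- rnorm(n)
  dat$x2 <- residuals(lm(raw ~ dat$x1 + dat$birthweight_adj))
  fr <- fit_bw_model(dat, "x1", binary = character(), model_id = "r")
  ff <- fit_bw_model(dat, c("x1", "x2"), binary = character(),
                     model_id = "f")
  tst <- nested_f_test(fr, ff)
  expect_lt(tst$F, 1e-16)
  expect_equal(tst$p, 1)

  dat$x2 <- rnorm(n)  # generic added predictor
  ff <- fit_bw_model(dat, c("x1", "x2"), binary = character(),
                     model_id = "f")
  tst <- nested_f_test(fr, ff)
  # algebraic identity: RSS form equals the R-squared form
  f_r2form <- ((ff$r2 - fr$r2) / tst$df1) / ((1 - ff$r2) / tst$df2)
  expect_equal(tst$F, f_r2form, tolerance = 1e-10)
  # independent route through stats::anova
  av <- anova(fr$lm, ff$lm)
  expect_equal(tst$F, av$F[2], tolerance = 1e-10)
  expect_equal(tst$p, av$`Pr(>F)`[2], tolerance = 1e-10)

  expect_error(nested_f_test(ff, fr), "nested")
})

test_that("adding the maternal score to the clinical model is detected at n = 549", {
  wins <- 0
  for (r in 1:10) {
    cfg <- model_generative_config("model3", seed = 700 + r)
    dat <- cohort_analysis_table(simulate_cohort(cfg))
    f2 <- fit_bw_model(dat, bw_model_predictors("model2"), model_id = "m2")
    f3 <- fit_bw_model(dat, bw_model_predictors("model3"), model_id = "m3")
    wins <- wins + (nested_f_test(f2, f3)$p < 0.001)
  }
  expect_gte(wins, 8)
})

test_that("F-test p-value is uniform under a pure-noise added predictor", {
  set.seed(54)
  ps <- replicate(200, {
    n <- 80
    dat <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
    dat$birthweight_adj <- 3500 + 70 * dat$x1 + rnorm(n, 0, 250)
    fr <- fit_bw_model(dat, "x1", binary = character())
    ff <- fit_bw_model(dat, c("x1", "x2"), binary = character())
    nested_f_test(fr, ff)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("VIF matches the closed form and car's implementation", {
  n <- 200
  # exactly orthogonal, mean-zero predictors: QR of a column-centered matrix
  set.seed(55)
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n), scale = FALSE)))
  dat <- tibble::tibble(a = Q[, 1], b = Q[, 2], c = Q[, 3],
                        birthweight_adj = rnorm(n, 3500, 400))
  f <- fit_bw_model(dat, c("a", "b", "c"), binary = character())
  expect_equal(vif_values(f)$vif, rep(1, 3), tolerance = 1e-10)

  # empirical correlation exactly 0.8 -> VIF = 1/(1-0.64) for both
  u <- Q[, 1] / sd(Q[, 1]); v <- Q[, 2] / sd(Q[, 2])
  dat2 <- tibble::tibble(x = u, y = 0.8 * u + sqrt(1 - 0.64) * v,
                         birthweight_adj = rnorm(n, 3500, 400))
  f2 <- fit_bw_model(dat2, c("x", "y"), binary = character())
  expect_equal(vif_values(f2)$vif, rep(1 / (1 - 0.64), 2),
               tolerance = 1e-8)

  skip_if_not_installed("car")
  expect_equal(vif_values(f2)$vif, unname(car::vif(f2$lm)),
               tolerance = 1e-8)
})

test_that("bootstrap R-squared intervals are deterministic, degenerate at exact fits, and cover the truth", {
  dat <- tibble::tibble(x = rnorm(60))
  dat$birthweight_adj <- 3000 + 100 * dat$x
  ci <- suppressWarnings(bootstrap_r2(dat, "x", binary = character(),
                                      n_boot = 100, seed = 2))
  expect_equal(c(ci$lower, ci$upper), c(1, 1))

  dat2 <- toy_analysis_table(150, seed = 8)
  a <- bootstrap_r2(dat2, c("maternal_score", "fetal_score"),
                    n_boot = 150, seed = 7)
  b <- bootstrap_r2(dat2, c("maternal_score", "fetal_score"),
                    n_boot = 150, seed = 7)
  expect_identical(a$replicates, b$replicates)
  expect_lte(a$lower, a$upper)
  expect_error(bootstrap_r2(dat2, "maternal_score", n_boot = 50), "100")

  # percentile-interval coverage of the known population R-squared
  true_r2 <- (81^2 + 69^2) / 444^2
  covered <- 0; n_sim <- 200
  for (r in seq_len(n_sim)) {
    cfg <- model_generative_config("model1", seed = 2000 + r)
    d <- cohort_analysis_table(simulate_cohort(cfg))
    ci <- bootstrap_r2(d, c("maternal_score", "fetal_score"),
                       n_boot = 200, seed = r)
    covered <- covered + (ci$lower <= true_r2 && true_r2 <= ci$upper)
  }
  expect_gte(covered / n_sim, 0.85)
})

test_that("residual diagnostics satisfy the OLS identities and find no structure in Gaussian data", {
  dat <- toy_analysis_table(1000, seed = 13)
  f <- fit_bw_model(dat, bw_model_predictors("model7"))
  dg <- residual_diagnostics(f)
  expect_lt(abs(sum(dg$data$residual)), 1e-8)
  X <- model.matrix(f$lm)
  expect_true(all(abs(crossprod(X, dg$data$residual)) < 1e-6))
  expect_lt(abs(dg$abs_resid_slope), 0.15)
  expect_lt(abs(dg$skewness), 0.3)
})

test_that("the model suite fits the ladder, tests the published pairs, and degrades gracefully", {
  dat <- toy_analysis_table(300, seed = 17)
  suite <- run_model_suite(dat, n_boot = 100, seed = 5)
  expect_length(suite$fits, 7)
  expect_equal(nrow(suite$nested), 5)
  expect_equal(nrow(suite$bootstrap), 7)
  expect_equal(nrow(suite$skipped), 0)
  # nested-R2 monotonicity along model2 < model4 < model5
  expect_gte(suite$fits$model4$r2, suite$fits$model2$r2)
  expect_gte(suite$fits$model5$r2, suite$fits$model4$r2)
  # parental-birthweight extension fitted on the complete subsample
  expect_false(is.null(suite$extra))
  expect_lt(suite$extra$parental_bw$n, nrow(dat))

  ser <- fig_r2_series(suite)
  expect_equal(ser$model, paste0("model", 1:7))
  expect_true(all(ser$lower <= ser$r2 + 1e-12 & ser$r2 <= ser$upper + 1e-12))

  # no fetal genotypes: models 1, 5, 7 skipped, others still run
  dat2 <- dat; dat2$fetal_score <- NULL
  suite2 <- run_model_suite(dat2, n_boot = 100, seed = 5)
  expect_setequal(suite2$skipped$model, c("model1", "model5", "model7"))
  expect_length(suite2$fits, 4)
})
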