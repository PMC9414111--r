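# Trio simulator: Hardy-Weinberg parents, Mendelian transmission, calibrated
# covariates and birthweight.

test_that("parental dosages follow Binomial(2, f), with hard boundaries", {
  g <- simulate_parental_genotypes(100, c(1 - 1e-12, 1e-12), seed = 1)
  expect_true(all(g$mother[, 1] == 2) && all(g$father[, 1] == 2))
  expect_true(all(g$mother[, 2] == 0) && all(g$father[, 2] == 0))

  g <- simulate_parental_genotypes(10000, 0.5, seed = 2)
  # closed-form binomial moments: mean 2f = 1, var 2f(1-f) = 0.5
  se_mean <- sqrt(0.5 / 10000)
  expect_lt(abs(mean(g$mother) - 1), 3 * se_mean)
  expect_lt(abs(var(as.vector(g$mother)) - 0.5), 0.05)

  expect_error(simulate_parental_genotypes(10, c(0.5, 1.2)),
               "SNP index 2")
  expect_error(simulate_parental_genotypes(10, NaN), "out of")
})

test_that("allele transmission is Mendelian with the exact het distribution", {
  expect_equal(transmit_alleles(matrix(0), matrix(0), seed = 1)[1, 1], 0L)
  expect_equal(transmit_alleles(matrix(2), matrix(0), seed = 1)[1, 1], 1L)
  expect_equal(transmit_alleles(matrix(2), matrix(2), seed = 1)[1, 1], 2L)

  n <- 10000
  kid <- transmit_alleles(matrix(1, n, 1), matrix(1, n, 1), seed = 3)
  props <- tabulate(kid + 1L, 3) / n
  # exact transmission probabilities (1/4, 1/2, 1/4)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) <
                    3 * sqrt(c(.25, .5, .25) * c(.75, .5, .75) / n)))

  expect_error(transmit_alleles(matrix(0.5), matrix(1)), "fractional")
  expect_error(transmit_alleles(matrix(3L), matrix(1L)), "0, 1, 2")
})

test_that("parent-child dosage correlation is 1/2 and allele frequency is conserved", {
  for (f in c(0.2, 0.5, 0.8)) {
    g <- simulate_trio_genotypes(4000, f, seed = round(100 * f))
    mc_se <- 1 / sqrt(4000)
    expect_lt(abs(cor(g$mother[, 1], g$child[, 1]) - 0.5), 3 * mc_se)
    expect_lt(abs(cor(g$father[, 1], g$child[, 1]) - 0.5), 3 * mc_se)
    # no drift: child-generation allele frequency matches the parents'
    se_f <- sqrt(f * (1 - f) / (2 * 4000))
    expect_lt(abs(mean(g$child[, 1]) / 2 - f), 3 * se_f)
  }
})

test_that("simulated covariates match the configured marginals", {
  covs <- simulate_covariates(50000, bw_cohort_marginals(), seed = 5)
  expect_lt(abs(mean(covs$maternal_height) - 165.0), 0.1)
  expect_lt(abs(sd(covs$maternal_height) - 6.4), 0.1)
  expect_lt(abs(mean(covs$smoking) - 0.146), 0.005)
  expect_lt(abs(mean(covs$primiparity) - 0.448), 0.008)
  expect_lt(abs(mean(covs$sex_male) - 0.522), 0.008)

  const <- simulate_covariates(100, list(x = list(mean = 5, sd = 0)),
                               seed = 1)
  expect_true(all(const$x == 5))

  expect_error(simulate_covariates(10, list(x = list(mean = 1))),
               "incomplete parameters.*x")
})

test_that("birthweight SD is calibrated to the configured total", {
  cfg0 <- sim_config(n_trios = 20000, beta_maternal_score = 0,
                     beta_fetal_score = 0, beta_paternal_score = 0,
                     clinical_effects = c(), seed = 6)
  coh <- simulate_cohort(cfg0)
  expect_lt(abs(sd(coh$phenotypes$birthweight) - 444), 7)
  # pure noise: any predictor explains ~nothing
  f <- fit_bw_model(cohort_analysis_table(coh), "maternal_score")
  expect_lt(f$r2, 0.002)

  # calibrated effects still leave marginal SD at the configured total
  cfg7 <- model_generative_config("model7", n_trios = 20000, seed = 7)
  coh7 <- simulate_cohort(cfg7)
  expect_lt(abs(sd(coh7$phenotypes$birthweight) - 444), 7)
})

test_that("direct-score mode reproduces the closed-form variance fractions", {
  # two-score model: population R2 = (81^2 + 69^2) / 444^2 = 0.0574
  cfg <- model_generative_config("model1", n_trios = 50000, seed = 8)
  dat <- cohort_analysis_table(simulate_cohort(cfg))
  f <- fit_bw_model(dat, c("maternal_score", "fetal_score"))
  expect_lt(abs(f$r2 - (81^2 + 69^2) / 444^2), 0.004)

  # five-covariate clinical model: systematic fraction = 0.2184
  cfg2 <- model_generative_config("model2", n_trios = 50000, seed = 9)
  dat2 <- cohort_analysis_table(simulate_cohort(cfg2))
  f2 <- fit_bw_model(dat2, bw_model_predictors("model2"))
  frac <- (38^2 + 125^2 + 87^2 + 280^2 * 0.146 * 0.854 +
             187^2 * 0.448 * 0.552) / 444^2
  expect_lt(abs(f2$r2 - frac), 0.006)
})

test_that("an over-committed effect budget reports the variance deficit", {
  expect_error(sim_config(beta_maternal_score = 400, beta_fetal_score = 400,
                          beta_paternal_score = 300),
               "deficit")
  cfg <- sim_config(seed = 1)
  cfg$total_bw_sd <- 100  # tamper past validation
  expect_error(simulate_birthweight(toy_analysis_table(50), cfg),
               "negative implied residual variance")
})

test_that("cohorts are bit-reproducible from the seed and differ across seeds", {
  a <- simulate_cohort(sim_config(n_trios = 80, seed = 42))
  b <- simulate_cohort(sim_config(n_trios = 80, seed = 42))
  c <- simulate_cohort(sim_config(n_trios = 80, seed = 43))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$scores, b$scores)
  expect_false(identical(a$phenotypes$birthweight,
                         c$phenotypes$birthweight))

  ga <- simulate_cohort(sim_config(n_trios = 40, mode = "genotype",
                                   n_snps = 30, seed = 11))
  gb <- simulate_cohort(sim_config(n_trios = 40, mode = "genotype",
                                   n_snps = 30, seed = 11))
  expect_identical(ga$genotypes$child, gb$genotypes$child)
  expect_identical(ga$weights, gb$weights)
})
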