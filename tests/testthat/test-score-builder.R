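# Score builder: weights I/O, variant filtering, allele alignment, score
# computation, standardization and validation.

test_that("weights tables round-trip and invariants are enforced", {
  w <- simulate_weights(25, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(as.data.frame(w2), as.data.frame(w), tolerance = 1e-12)

  dup <- w; dup$snp_id[2] <- dup$snp_id[1]
  write_weights(dup, path)
  expect_error(read_weights(path), "duplicate snp_id")

  same <- w; same$other_allele[3] <- same$effect_allele[3]
  write_weights(same, path)
  expect_error(read_weights(path), "effect_allele equals other_allele")

  nocol <- w; nocol$imputation_r2 <- NULL
  write_weights(nocol, path)
  expect_error(read_weights(path), "imputation_r2")

  writeLines(paste(names(w), collapse = "\t"), path)
  expect_warning(empty <- read_weights(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("MAF/imputation filter applies strict inequalities on both predicates", {
  w <- toy_filter_weights()
  res <- filter_variants(w, maf_min = 0.001, info_min = 0.4)
  expect_equal(res$retained$snp_id, c("rs3", "rs4"))
  expect_equal(nrow(res$excluded), 3)
  expect_true(all(nzchar(res$excluded$reason)))

  # vacuous thresholds retain everything (all frequencies are in (0,1))
  expect_equal(nrow(filter_variants(w, 0, 0)$retained), nrow(w))

  # boundary convention: MAF exactly at the threshold is excluded
  b <- w[3, ]; b$effect_allele_freq <- 0.999; b$imputation_r2 <- 0.9
  expect_warning(res_b <- filter_variants(b, 0.001, 0.4), "no variants pass")
  expect_equal(nrow(res_b$retained), 0)

  lowall <- w[1:2, ]
  expect_warning(filter_variants(lowall, 0.5, 0.99), "no variants pass")
})

test_that("dosages are aligned to the effect allele in either orientation", {
  weights <- tibble::tibble(
    snp_id = c("s1", "s2", "s3"), chrom = "1", pos = 1:3,
    effect_allele = c("A", "G", "C"), other_allele = c("G", "A", "T"),
    effect_allele_freq = 0.5, imputation_r2 = 1,
    weight_maternal_adj = 1, weight_fetal_adj = 1, weight_fetal_unadj = 1)
  variants <- tibble::tibble(
    snp_id = c("s1", "s2", "s3"),
    counted_allele = c("A", "A", "T"),  # s1 matches, s2 and s3 flipped
    other_allele = c("G", "G", "C"))
  d <- matrix(c(1.4, 2, 0.5), 1, dimnames = list(NULL, c("s1", "s2", "s3")))
  al <- align_dosages(d, variants, weights)
  expect_equal(unname(al$dosages[1, ]), c(1.4, 0, 1.5))
  expect_equal(unname(al$flipped), c(FALSE, TRUE, TRUE))

  bad <- variants; bad$counted_allele[1] <- "T"
  expect_error(align_dosages(d, bad, weights), "allele mismatch.*s1")

  expect_error(align_dosages(d[, 1:2, drop = FALSE], variants[1:2, ],
                             weights), "absent from genotypes")
  expect_warning(al2 <- align_dosages(d[, 1:2, drop = FALSE], variants[1:2, ],
                                      weights, allow_missing = TRUE),
                 "dropped")
  expect_equal(ncol(al2$dosages), 2)

  amb <- weights; amb$effect_allele[1] <- "A"; amb$other_allele[1] <- "T"
  va <- variants; va$counted_allele[1] <- "A"; va$other_allele[1] <- "T"
  expect_warning(align_dosages(d, va, amb), "strand-ambiguous")
  expect_warning(al3 <- align_dosages(d, va, amb, strict = TRUE),
                 "dropping")
  expect_equal(al3$weights$snp_id, c("s2", "s3"))
})

test_that("scores are weighted allele sums, linear in the weights, with HWE imputation of missing dosages", {
  w <- simulate_weights(3, seed = 2)
  w$weight_fetal_adj <- c(0.02, -0.01, 0.03)
  g <- matrix(c(1, 2, 0), 1, dimnames = list(NULL, w$snp_id))
  expect_equal(compute_score(g, w, "weight_fetal_adj"), 0.00)

  w0 <- w; w0$weight_fetal_adj <- 0
  expect_equal(compute_score(g, w0, "weight_fetal_adj"), 0)

  w1 <- simulate_weights(1, seed = 3); w1$weight_fetal_adj <- 1
  g1 <- matrix(2, 1, dimnames = list(NULL, w1$snp_id))
  expect_equal(compute_score(g1, w1, "weight_fetal_adj"), 2)

  # linearity over weight columns on shared dosages
  w$weight_maternal_adj <- c(0.5, 1, -2)
  wsum <- w; wsum$weight_fetal_unadj <- w$weight_maternal_adj +
    w$weight_fetal_adj
  gmat <- matrix(sample(0:2, 30, TRUE), 10,
                 dimnames = list(NULL, w$snp_id))
  expect_equal(compute_score(gmat, wsum, "weight_fetal_unadj"),
               compute_score(gmat, w, "weight_maternal_adj") +
                 compute_score(gmat, w, "weight_fetal_adj"))

  # missing dosage imputed as 2f
  w$effect_allele_freq <- c(0.25, 0.5, 0.75)
  gna <- matrix(c(NA, 2, 0), 1, dimnames = list(NULL, w$snp_id))
  expect_equal(compute_score(gna, w, "weight_fetal_adj"),
               0.02 * 0.5 - 0.01 * 2 + 0)

  wna <- w; wna$weight_fetal_adj <- NA_real_
  expect_error(compute_score(gmat, wna, "weight_fetal_adj"), "all weights")
})

test_that("standardization gives mean 0 / SD 1 with the n-1 denominator", {
  expect_equal(standardize_score(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize_score(rnorm(500, 20, 7))
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1)
  expect_error(standardize_score(rep(2, 10)), "constant")
  expect_error(standardize_score(3), "at least 2")
})

test_that("score validation matches the closed-form cov/var slope", {
  s <- standardize_score(rnorm(50))
  v0 <- suppressWarnings(validate_score(s, s))  # exact fit
  expect_equal(v0$slope, 1)
  expect_equal(v0$r2, 1)

  set.seed(31)
  x <- standardize_score(rnorm(40))
  y <- 3000 + 50 * x + rnorm(40, 0, 100)
  v <- validate_score(x, y)
  expect_equal(v$slope, cov(x, y) / var(x), tolerance = 1e-10)

  expect_error(validate_score(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("genotype-derived scores predict simulated birthweight at the study scale", {
  hits <- 0; reps <- 30
  for (r in seq_len(reps)) {
    cfg <- model_generative_config("model1", n_trios = 549, seed = 900 + r,
                                   mode = "genotype", n_snps = 80)
    coh <- simulate_cohort(cfg)
    vm <- validate_score(coh$scores$maternal_score,
                         coh$phenotypes$birthweight)
    vf <- validate_score(coh$scores$fetal_score,
                         coh$phenotypes$birthweight)
    hits <- hits + (vm$slope > 0 && vm$p < 0.05) +
      (vf$slope > 0 && vf$p < 0.05)
  }
  expect_gte(hits / (2 * reps), 0.9)
})

test_that("scores are invariant to flipping every allele label in the genotype file", {
  cfg <- sim_config(n_trios = 60, n_snps = 25, mode = "genotype", seed = 21)
  coh <- simulate_cohort(cfg)
  w <- coh$weights
  variants <- tibble::tibble(snp_id = w$snp_id,
                             counted_allele = w$effect_allele,
                             other_allele = w$other_allele)
  d <- coh$genotypes$mother
  suppressWarnings({
    a1 <- align_dosages(d, variants, w)
    s1 <- compute_score(a1$dosages, a1$weights, "weight_maternal_adj")
  })

  flipped <- tibble::tibble(snp_id = w$snp_id,
                            counted_allele = w$other_allele,
                            other_allele = w$effect_allele)
  suppressWarnings({
    a2 <- align_dosages(2 - d, flipped, w)
    s2 <- compute_score(a2$dosages, a2$weights, "weight_maternal_adj")
  })
  expect_equal(s1, s2, tolerance = 1e-12)
})
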