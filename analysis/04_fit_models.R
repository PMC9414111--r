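#!/usr/bin/env Rscript

# Step 4 — fit the seven nested models and the parental-birthweight
# extensions.
#
# Per-SD coefficients with 95% t-intervals, R2 / Adj-R2, the published
# nested F-test comparisons (3v2, 4v2, 5v4, 6v4, 7v4), bootstrap percentile
# intervals for each model's R2, VIF, and a sensitivity re-run of the
# two-score model with unfiltered vs filtered score SNPs.

suppressPackageStartupMessages(library(bwtrio))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 20260930L

cohort <- tibble::as_tibble(utils::read.delim("results/analysis_cohort.tsv"))
scores <- tibble::as_tibble(utils::read.delim("results/scores.tsv"))
dat <- merge(cohort, scores, by = "trio_id", sort = FALSE)

suite <- run_model_suite(dat, n_boot = 1000, seed = seed)
print(suite)

write_model_report(suite, "results/model_report.tsv")
utils::write.table(fig_r2_series(suite), "results/r2_series.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(suite$nested, "results/nested_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(suite$vif, "results/vif.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
write_suite_summary(suite, "results/suite_summary.json")

cat("\nVIF range across models: ",
    sprintf("%.2f - %.2f", min(suite$vif$vif), max(suite$vif$vif)),
    " (values near 1 indicate little collinearity)\n", sep = "")
dg <- residual_diagnostics(suite$fits$model7)
cat(sprintf("Model 7 residuals: skewness %.3f, |resid|-on-fitted slope %.3f\n",
            dg$skewness, dg$abs_resid_slope))
if (!is.null(suite$extra)) {
  cat(sprintf("\nParental-birthweight subsample (n = %d): Adj-R2 %.3f without, %.3f with the fetal score\n",
              suite$extra$parental_bw$n, suite$extra$parental_bw$adj_r2,
              suite$extra$parental_bw_fetal$adj_r2))
}

# Sensitivity: rebuild the fetal/maternal scores without the variant filter
# and compare the two-score model fit; the difference should be negligible.
weights <- read_weights("results/data/weights.tsv")
geno <- read_trio_vcf("results/data/cohort.vcf",
                      "results/data/cohort_trios.tsv")
keep <- match(dat$trio_id, geno$trio_ids)
unfiltered <- tibble::tibble(
  birthweight_adj = dat$birthweight_adj,
  maternal_score = standardize_score(compute_score(
    geno$mother, weights, "weight_maternal_adj"))[keep],
  fetal_score = standardize_score(compute_score(
    geno$child, weights, "weight_fetal_adj"))[keep]
)
f_filt <- fit_bw_model(dat, c("maternal_score", "fetal_score"))
f_all <- fit_bw_model(unfiltered, c("maternal_score", "fetal_score"))
cat(sprintf("\nSensitivity (two-score model): R2 %.4f with the variant filter, %.4f without (delta %.4f)\n",
            f_filt$r2, f_all$r2, f_all$r2 - f_filt$r2))

cat("\nWrote results/model_report.tsv, r2_series.tsv, nested_tests.tsv, vif.tsv, suite_summary.json\n")
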