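#!/usr/bin/env Rscript

# Step 1 — simulate the synthetic trio cohort.
#
# Generates a 549-trio, 209-SNP cohort in genotype mode: Hardy-Weinberg
# parents, Mendelian transmission to the child, a synthetic variant-weights
# panel, clinical covariates with the published marginals, and birthweight
# from the full joint-model effect sizes plus gestational-age and sex
# effects (so the downstream adjustment step has real work to do).
# Writes VCF + trio map + phenotypes + weights under results/data/.

suppressPackageStartupMessages(library(bwtrio))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 20260930L

clin <- bw_model_effects("model7")
clin <- clin[setdiff(names(clin), c("maternal_score", "fetal_score"))]
clin <- c(clin, gestational_age = 180, sex_male = 130)  # g/SD and g/category

cfg <- sim_config(n_trios = 549, n_snps = 209, mode = "genotype",
                  clinical_effects = clin, seed = seed)
print(cfg)

cohort <- simulate_cohort(cfg)
print(cohort)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
paths <- write_dataset(cohort, "results/data")
write_weights(cohort$weights, "results/data/weights.tsv")

cat("\nWrote:\n")
for (p in c(paths, "results/data/weights.tsv")) cat(" ", p, "\n")
cat(sprintf("Seed: %d (re-run with the same seed for byte-identical files)\n",
            seed))
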