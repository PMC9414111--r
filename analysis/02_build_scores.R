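#!/usr/bin/env Rscript

# Step 2 — construct the maternal, fetal and paternal genetic scores.
#
# Reads the weights panel and the trio VCF written by step 1, applies the
# MAF > 0.001 / imputation-quality > 0.4 variant filter, aligns dosages to
# the effect allele, computes the three weighted allele-sum scores,
# standardizes them, and validates each against its phenotype (offspring
# birthweight for the maternal and fetal scores, father's own birthweight
# for the paternal score).

suppressPackageStartupMessages(library(bwtrio))

weights <- read_weights("results/data/weights.tsv")
flt <- filter_variants(weights, maf_min = 0.001, info_min = 0.4)
cat(sprintf("Variant filter: %d of %d SNPs retained (%d excluded)\n",
            nrow(flt$retained), nrow(weights), nrow(flt$excluded)))
if (nrow(flt$excluded)) print(as.data.frame(flt$excluded))

geno <- read_trio_vcf("results/data/cohort.vcf",
                      "results/data/cohort_trios.tsv")
aligned <- lapply(geno[c("mother", "father", "child")], function(d)
  align_dosages(d, geno$variants, flt$retained)$dosages)
scores <- tibble::tibble(
  trio_id = geno$trio_ids,
  maternal_score = standardize_score(
    compute_score(aligned$mother, flt$retained, "weight_maternal_adj")),
  fetal_score = standardize_score(
    compute_score(aligned$child, flt$retained, "weight_fetal_adj")),
  paternal_score = standardize_score(
    compute_score(aligned$father, flt$retained, "weight_fetal_unadj"))
)
write_scores(scores, "results/scores.tsv")

ph <- read_phenotypes("results/data/cohort_phenotypes.tsv")
stopifnot(identical(ph$trio_id, scores$trio_id))
val <- rbind(
  cbind(score = "maternal", validate_score(scores$maternal_score,
                                           ph$birthweight)),
  cbind(score = "fetal", validate_score(scores$fetal_score,
                                        ph$birthweight)),
  cbind(score = "paternal", validate_score(scores$paternal_score,
                                           ph$paternal_own_birthweight))
)
utils::write.table(val, "results/score_validation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nScore validation (slope in g per 1 SD of score):\n")
print(as.data.frame(val), digits = 3)
cat("\nWrote results/scores.tsv and results/score_validation.tsv\n")
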