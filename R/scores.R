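REQUIRED_WEIGHT_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "effect_allele_freq", "imputation_r2",
  "weight_maternal_adj", "weight_fetal_adj", "weight_fetal_unadj"
)

#' Read a variant-weights table
#'
#' Parses the tab-separated weights table that drives score construction: one
#' row per SNP with its alleles, effect-allele frequency, imputation quality
#' and three per-allele weight columns (maternal effect adjusted for fetal
#' genotype, fetal effect adjusted for maternal genotype, and the unadjusted
#' fetal effect used for the paternal score).
#'
#' @param path Path to a TSV file with a header naming at least the columns
#'   in `REQUIRED_WEIGHT_COLS`.
#' @return Tibble of validated variant weights.
#' @export
read_weights <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("weights table at ", path, " is empty")
    raw <- raw[, intersect(REQUIRED_WEIGHT_COLS, names(raw)), drop = FALSE]
    return(tibble::as_tibble(raw))
  }
  validate_weights(tibble::as_tibble(raw))
}

validate_weights <- function(w) {
  missing_cols <- setdiff(REQUIRED_WEIGHT_COLS, names(w))
  if (length(missing_cols))
    stop("weights table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- w$snp_id[duplicated(w$snp_id)]
  if (length(dup))
    stop("duplicate snp_id in weights table: ",
         paste(unique(dup), collapse = ", "))
  same <- w$effect_allele == w$other_allele
  if (any(same))
    stop("effect_allele equals other_allele for: ",
         paste(w$snp_id[same], collapse = ", "))
  wt <- as.matrix(w[, c("weight_maternal_adj", "weight_fetal_adj",
                        "weight_fetal_unadj")])
  if (any(!is.finite(wt)))
    stop("non-finite weight values in weights table")
  check_freqs(w$effect_allele_freq, "effect_allele_freq")
  w$chrom <- as.character(w$chrom)
  w
}

#' Write a variant-weights table
#' @param weights Weights tibble (see [read_weights()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter score variants on MAF and imputation quality
#'
#' Retains variants with minor allele frequency strictly greater than
#' `maf_min` AND imputation quality strictly greater than `info_min`
#' (strict inequalities, matching the published "> 0.001" / "> 0.4" wording;
#' MAF is `min(f, 1 - f)` of the effect-allele frequency).
#'
#' @param weights Weights tibble.
#' @param maf_min Minor-allele-frequency threshold in \[0, 1\] (default 0.001).
#' @param info_min Imputation-quality threshold in \[0, 1\] (default 0.4).
#' @return List with `retained` (weights tibble) and `excluded` (tibble of
#'   `snp_id`, `maf`, `imputation_r2`, `reason`).
#' @export
#' @examples
#' w <- simulate_weights(20, seed = 1)
#' filter_variants(w)$excluded
filter_variants <- function(weights, maf_min = 0.001, info_min = 0.4) {
  stopifnot(maf_min >= 0, maf_min <= 1, info_min >= 0, info_min <= 1)
  maf <- pmin(weights$effect_allele_freq, 1 - weights$effect_allele_freq)
  # strict inequality, with a tiny guard so that values equal to the
  # threshold up to floating-point representation (e.g. 1 - 0.999) are
  # treated as at the boundary and excluded
  ok_maf <- maf - maf_min > 1e-9
  ok_info <- weights$imputation_r2 - info_min > 1e-9
  keep <- ok_maf & ok_info
  r_maf <- ifelse(ok_maf, NA_character_,
                  sprintf("MAF %.4g <= %.4g", maf, maf_min))
  r_info <- ifelse(ok_info, NA_character_,
                   sprintf("imputation r2 %.3g <= %.3g",
                           weights$imputation_r2, info_min))
  reason <- mapply(function(a, b) paste(stats::na.omit(c(a, b)),
                                        collapse = "; "), r_maf, r_info)
  excluded <- tibble::tibble(snp_id = weights$snp_id[!keep],
                             maf = maf[!keep],
                             imputation_r2 = weights$imputation_r2[!keep],
                             reason = reason[!keep])
  if (!any(keep)) warning("no variants pass the MAF/imputation filter")
  list(retained = weights[keep, , drop = FALSE], excluded = excluded)
}

# A/T and C/G SNPs cannot be disambiguated across strand flips
is_strand_ambiguous <- function(a1, a2) {
  p <- paste0(pmin(a1, a2), pmax(a1, a2))
  p %in% c("AT", "CG")
}

#' Align a dosage matrix to the effect alleles of a weights table
#'
#' The score formula presumes dosages count the effect allele. For each
#' weights SNP, the genotype file's counted allele is compared with the
#' weight's allele pair: matching orientation keeps the dosage, flipped
#' orientation (counted allele equals the other allele) replaces it by
#' `2 - dosage`, anything else is an error. Strand-ambiguous (A/T, C/G) SNPs
#' are retained with a warning unless `strict = TRUE` drops them.
#'
#' @param dosages Numeric matrix (individuals x SNPs) whose columns are
#'   named by SNP id and count `variants$counted_allele`.
#' @param variants Tibble describing the genotype file's variants:
#'   `snp_id`, `counted_allele`, `other_allele`.
#' @param weights Weights tibble (post-filtering).
#' @param allow_missing If `TRUE`, weights SNPs absent from the genotypes are
#'   dropped (with a warning) instead of raising an error.
#' @param strict Drop strand-ambiguous SNPs instead of warning.
#' @return List: `dosages` (matrix aligned to and ordered as `weights`),
#'   `weights` (possibly reduced), `flipped` (logical per retained SNP).
#' @export
align_dosages <- function(dosages, variants, weights,
                          allow_missing = FALSE, strict = FALSE) {
  stopifnot(!is.null(colnames(dosages)))
  ambig <- is_strand_ambiguous(weights$effect_allele, weights$other_allele)
  if (any(ambig)) {
    if (strict) {
      warning("dropping ", sum(ambig), " strand-ambiguous (A/T, C/G) SNP(s): ",
              paste(utils::head(weights$snp_id[ambig], 5), collapse = ", "))
      weights <- weights[!ambig, , drop = FALSE]
    } else {
      warning(sum(ambig), " strand-ambiguous (A/T, C/G) SNP(s) retained; ",
              "orientation assumed to match the genotype file")
    }
  }
  present <- weights$snp_id %in% variants$snp_id
  if (!all(present)) {
    msg <- paste("weights SNP(s) absent from genotypes:",
                 paste(utils::head(weights$snp_id[!present], 5),
                       collapse = ", "))
    if (!allow_missing) stop(msg)
    warning(msg, " (dropped)")
    weights <- weights[present, , drop = FALSE]
  }
  idx <- match(weights$snp_id, variants$snp_id)
  counted <- variants$counted_allele[idx]
  other <- variants$other_allele[idx]
  same <- counted == weights$effect_allele & other == weights$other_allele
  flip <- counted == weights$other_allele & other == weights$effect_allele
  bad <- !(same | flip)
  if (any(bad))
    stop("allele mismatch for SNP(s) ",
         paste(sprintf("%s (weights %s/%s vs genotypes %s/%s)",
                       weights$snp_id[bad], weights$effect_allele[bad],
                       weights$other_allele[bad], counted[bad], other[bad])[
                         seq_len(min(5, sum(bad)))], collapse = "; "))
  d <- dosages[, weights$snp_id, drop = FALSE]
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  list(dosages = d, weights = weights, flipped = flip)
}

#' Compute raw genetic scores from aligned dosages
#'
#' Per person, the score is the weighted sum of effect-allele dosages,
#' `GS = sum_i w_i * g_i`, over the SNPs of the weights table. Missing
#' dosages are imputed as `2 * effect_allele_freq` (the Hardy-Weinberg
#' expectation), standard polygenic-score practice.
#'
#' @param aligned_dosages Numeric matrix (individuals x SNPs), columns named
#'   by SNP id and counting the effect allele.
#' @param weights Weights tibble.
#' @param weight_column Which weight column to use: `"weight_maternal_adj"`,
#'   `"weight_fetal_adj"` or `"weight_fetal_unadj"`.
#' @return Numeric vector of raw scores (same units as the weights).
#' @export
#' @examples
#' w <- simulate_weights(3, seed = 1)
#' g <- matrix(rep(1, 6), 2, dimnames = list(NULL, w$snp_id))
#' compute_score(g, w, "weight_fetal_adj")
compute_score <- function(aligned_dosages, weights,
                          weight_column = c("weight_maternal_adj",
                                            "weight_fetal_adj",
                                            "weight_fetal_unadj")) {
  weight_column <- match.arg(weight_column)
  wv <- weights[[weight_column]]
  if (all(is.na(wv))) stop("all weights missing in column ", weight_column)
  d <- aligned_dosages[, weights$snp_id, drop = FALSE]
  if (anyNA(d)) {
    imp <- matrix(2 * weights$effect_allele_freq, nrow = nrow(d),
                  ncol = ncol(d), byrow = TRUE)
    d[is.na(d)] <- imp[is.na(d)]
  }
  drop(d %*% wv)
}

#' Standardize a raw score to mean 0 and SD 1
#'
#' Uses the sample mean and the n-1 sample SD of the analysis sample.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Standardized numeric vector.
#' @export
#' @examples
#' standardize_score(c(1, 2, 3))
standardize_score <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations to standardize")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("score is constant (SD = 0) and cannot be standardized")
  (x - mean(x)) / s
}

#' Validate a genetic score against its phenotype
#'
#' Simple linear regression of the phenotype on the standardized score;
#' reports the slope (= covariance/variance), its SE, t, p and R-squared.
#'
#' @param score Standardized score vector.
#' @param phenotype Paired phenotype vector (complete cases used; n >= 3
#'   required).
#' @return Tibble with one row: `slope`, `se`, `t`, `p`, `r2`, `n`.
#' @export
validate_score <- function(score, phenotype) {
  ok <- is.finite(score) & is.finite(phenotype)
  score <- score[ok]; phenotype <- phenotype[ok]
  if (length(score) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(score) == 0) stop("degenerate (constant) score predictor")
  fit <- stats::lm(phenotype ~ score)
  sm <- summary(fit)
  tibble::tibble(slope = sm$coefficients["score", "Estimate"],
                 se = sm$coefficients["score", "Std. Error"],
                 t = sm$coefficients["score", "t value"],
                 p = sm$coefficients["score", "Pr(>|t|)"],
                 r2 = sm$r.squared,
                 n = length(score))
}

#' Build the three trio genetic scores from genotypes and weights
#'
#' Maternal score: mother's dosages weighted by the maternal-adjusted
#' weights. Fetal score: child's dosages weighted by the fetal-adjusted
#' weights. Paternal score: father's dosages weighted by the unadjusted
#' fetal weights (a fetal-type score for the father's own birthweight).
#' Each score is standardized to mean 0, SD 1 in the sample.
#'
#' @param genotypes A `bw_trio_genotypes` (effect-allele dosage matrices) or
#'   the result of [read_trio_vcf()] after [align_dosages()].
#' @param weights Weights tibble (post-filtering).
#' @return Tibble: `trio_id` (if available), `maternal_score`, `fetal_score`,
#'   `paternal_score` (standardized).
#' @export
build_scores <- function(genotypes, weights) {
  cols <- c(maternal_score = "weight_maternal_adj",
            fetal_score = "weight_fetal_adj",
            paternal_score = "weight_fetal_unadj")
  member <- c(maternal_score = "mother", fetal_score = "child",
              paternal_score = "father")
  out <- lapply(names(cols), function(nm)
    standardize_score(compute_score(genotypes[[member[[nm]]]], weights,
                                    cols[[nm]])))
  names(out) <- names(cols)
  tibble::as_tibble(out)
}

#' Write scores to TSV
#' @param scores Tibble with `trio_id` and score columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
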