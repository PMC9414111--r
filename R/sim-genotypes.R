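#' Simulate parental genotypes under Hardy-Weinberg equilibrium
#'
#' Each parent's dosage at SNP i counts copies of the effect allele and is
#' drawn as Binomial(2, f_i); mothers and fathers are independent, and SNPs
#' are independent (no linkage disequilibrium).
#'
#' @param n_trios Number of trios (>= 1).
#' @param allele_freqs Effect-allele frequencies, each strictly in (0, 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with integer matrices `mother` and `father`
#'   (`n_trios` x `n_snps`, entries 0/1/2).
#' @export
#' @examples
#' g <- simulate_parental_genotypes(5, c(0.2, 0.5), seed = 1)
#' dim(g$mother)
simulate_parental_genotypes <- function(n_trios, allele_freqs, seed = NULL) {
  stopifnot(n_trios >= 1)
  check_freqs(allele_freqs)
  draw <- function() {
    m <- vapply(allele_freqs,
                function(f) stats::rbinom(n_trios, 2L, f),
                integer(n_trios))
    matrix(as.integer(m), nrow = n_trios)
  }
  run <- function() list(mother = draw(), father = draw())
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Transmit one allele from each parent to the child
#'
#' Mendelian transmission at independent SNPs: a homozygous parent
#' contributes its allele deterministically; a heterozygote contributes the
#' effect allele with probability 1/2. The child dosage is the sum of the two
#' contributions, so trio genotypes are always Mendelian-consistent and the
#' expected parent-child dosage correlation is 1/2.
#'
#' @param mother,father Integer dosage matrices with entries in \{0, 1, 2\}.
#' @param seed Optional integer seed.
#' @return Integer matrix of child dosages, same shape as the parents.
#' @export
#' @examples
#' transmit_alleles(matrix(2), matrix(0))  # obligate heterozygote
transmit_alleles <- function(mother, father, seed = NULL) {
  mother <- as.matrix(mother); father <- as.matrix(father)
  if (!identical(dim(mother), dim(father)))
    stop("mother and father dosage matrices must have the same shape")
  for (m in list(mother, father))
    if (any(!is.finite(m)) || any(m != floor(m)) || any(m < 0 | m > 2))
      stop("parental dosages must be integers in {0, 1, 2}; ",
           "allele transmission is undefined for fractional dosages")
  run <- function() {
    gamete <- function(g) {
      # P(transmit effect allele) = g/2 for g in {0,1,2}
      matrix(stats::rbinom(length(g), 1L, g / 2), nrow = nrow(g))
    }
    child <- gamete(mother) + gamete(father)
    storage.mode(child) <- "integer"
    dimnames(child) <- dimnames(mother)
    child
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full set of trio genotypes
#'
#' Convenience wrapper: Hardy-Weinberg parents plus Mendelian transmission.
#'
#' @inheritParams simulate_parental_genotypes
#' @param snp_ids Optional SNP identifiers used as column names.
#' @return List of class `bw_trio_genotypes` with matrices `mother`,
#'   `father`, `child` and the vector `allele_freqs`.
#' @export
simulate_trio_genotypes <- function(n_trios, allele_freqs, snp_ids = NULL,
                                    seed = NULL) {
  run <- function() {
    par <- simulate_parental_genotypes(n_trios, allele_freqs)
    child <- transmit_alleles(par$mother, par$father)
    g <- list(mother = par$mother, father = par$father, child = child,
              allele_freqs = allele_freqs)
    if (!is.null(snp_ids)) {
      stopifnot(length(snp_ids) == length(allele_freqs))
      for (nm in c("mother", "father", "child")) colnames(g[[nm]]) <- snp_ids
    }
    structure(g, class = "bw_trio_genotypes")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a synthetic variant-weights table
#'
#' Generates a plausible stand-in for a published birthweight SNP panel:
#' rs-style identifiers, distinct alleles, effect-allele frequencies,
#' per-SNP imputation quality, and three per-allele weight columns in grams
#' (maternal effect adjusted for fetal genotype, fetal effect adjusted for
#' maternal genotype, and the unadjusted fetal effect used for the paternal
#' score). A small fraction of SNPs (default 2%) is given low frequency or
#' low imputation quality so that the MAF/quality filters have work to do,
#' mirroring the reported "98% of score SNPs pass" situation.
#'
#' @param n_snps Number of SNPs (default 209).
#' @param weight_sd SD of the per-allele weights in grams (default 15).
#' @param frac_lowqual Fraction of SNPs made rare or poorly imputed.
#' @param seed Optional integer seed.
#' @return A tibble with the columns required by [read_weights()].
#' @export
#' @examples
#' w <- simulate_weights(10, seed = 1)
#' names(w)
simulate_weights <- function(n_snps = 209, weight_sd = 15,
                             frac_lowqual = 0.02, seed = NULL) {
  run <- function() {
    bases <- c("A", "C", "G", "T")
    eff <- sample(bases, n_snps, replace = TRUE)
    oth <- vapply(eff, function(a) sample(setdiff(bases, a), 1), "")
    freq <- stats::runif(n_snps, 0.05, 0.95)
    info <- stats::runif(n_snps, 0.7, 1.0)
    n_low <- max(0L, round(frac_lowqual * n_snps))
    if (n_low > 0) {
      idx <- sample.int(n_snps, n_low)
      half <- idx[seq_len(ceiling(n_low / 2))]
      freq[half] <- stats::runif(length(half), 1e-5, 9e-4)   # below MAF cut
      rest <- setdiff(idx, half)
      info[rest] <- stats::runif(length(rest), 0.05, 0.35)   # below info cut
    }
    w_fet <- stats::rnorm(n_snps, 0, weight_sd)
    tibble::tibble(
      snp_id = sprintf("rs%07d", sample.int(9e6, n_snps)),
      chrom = as.character(rep_len(1:22, n_snps)),
      pos = seq_len(n_snps) * 1000L + 12345L,
      effect_allele = unname(eff),
      other_allele = unname(oth),
      effect_allele_freq = freq,
      imputation_r2 = info,
      weight_maternal_adj = stats::rnorm(n_snps, 0, weight_sd),
      weight_fetal_adj = w_fet,
      weight_fetal_unadj = w_fet + stats::rnorm(n_snps, 0, weight_sd / 3)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
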