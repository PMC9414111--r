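# Synthetic parental own-birthweight parameters (plumbing for the
# additional-models subsample; see the methods vignette).
PARENT_BW_MEAN <- c(mother = 3400, father = 3500)
PARENT_BW_SD <- 500
PARENT_BW_SCORE_EFFECT <- c(mother = 80, father = 120)  # g per SD of own score

#' Simulate clinical and anthropometric covariates
#'
#' Continuous covariates are drawn from independent normal distributions with
#' the configured mean/SD; binary covariates are Bernoulli with the
#' configured prevalence. Covariates are mutually independent.
#'
#' @param n Number of individuals/trios.
#' @param covariate_params Named list of `list(mean=, sd=)` or
#'   `list(prevalence=)` entries; see [bw_cohort_marginals()].
#' @param seed Optional integer seed.
#' @return Tibble with one column per covariate (binary columns are
#'   integer 0/1).
#' @export
#' @examples
#' simulate_covariates(3, bw_cohort_marginals(), seed = 1)
simulate_covariates <- function(n, covariate_params, seed = NULL) {
  stopifnot(n >= 1)
  bad <- vapply(covariate_params, function(p)
    is.null(p$prevalence) && (is.null(p$mean) || is.null(p$sd)), TRUE)
  if (any(bad))
    stop("incomplete parameters (need mean/sd or prevalence) for covariate(s): ",
         paste(names(covariate_params)[bad], collapse = ", "))
  run <- function() {
    cols <- lapply(covariate_params, function(p) {
      if (!is.null(p$prevalence)) stats::rbinom(n, 1L, p$prevalence)
      else stats::rnorm(n, p$mean, p$sd)
    })
    tibble::as_tibble(cols)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate raw birthweight from predictors and a calibrated effect model
#'
#' Birthweight is the configured mean plus each effect times its predictor on
#' the reporting scale (continuous covariates standardized by their
#' configured mean/SD; binary covariates and standardized scores taken as
#' is), plus a Gaussian residual whose SD is calibrated so that the marginal
#' birthweight SD equals `config$total_bw_sd` under the independence
#' assumption.
#'
#' @param predictors Tibble/data frame containing a column for every effect
#'   named in `config$clinical_effects`, plus `maternal_score`,
#'   `fetal_score`, `paternal_score` columns for any nonzero score effect.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of birthweights in grams.
#' @export
simulate_birthweight <- function(predictors, config, seed = NULL) {
  stopifnot(inherits(config, "bw_sim_config"))
  sv <- systematic_variance(config)
  if (sv > config$total_bw_sd^2)
    stop(sprintf(paste0("negative implied residual variance: systematic ",
                        "variance %.1f g^2 exceeds total %.1f g^2 ",
                        "(deficit %.1f g^2)"),
                 sv, config$total_bw_sd^2, sv - config$total_bw_sd^2))
  score_betas <- c(maternal_score = config$beta_maternal_score,
                   fetal_score = config$beta_fetal_score,
                   paternal_score = config$beta_paternal_score)
  score_betas <- score_betas[score_betas != 0]
  needed <- c(names(config$clinical_effects), names(score_betas))
  absent <- setdiff(needed, names(predictors))
  if (length(absent))
    stop("predictors missing column(s): ", paste(absent, collapse = ", "))

  n <- nrow(predictors)
  mu <- rep(config$bw_mean, n)
  for (nm in names(config$clinical_effects)) {
    b <- config$clinical_effects[[nm]]
    p <- config$covariate_params[[nm]]
    x <- predictors[[nm]]
    if (!is.null(p$prevalence)) {
      mu <- mu + b * x
    } else {
      if (p$sd == 0 && b != 0)
        stop("covariate ", nm, " has SD 0; a per-SD effect is undefined")
      if (b != 0) mu <- mu + b * (x - p$mean) / p$sd
    }
  }
  for (nm in names(score_betas)) mu <- mu + score_betas[[nm]] * predictors[[nm]]

  resid_sd <- sqrt(config$total_bw_sd^2 - sv)
  run <- function() mu + stats::rnorm(n, 0, resid_sd)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete synthetic trio cohort
#'
#' Runs the whole generator: covariates, genetic scores (drawn directly in
#' `"direct"` mode, or computed from Hardy-Weinberg/Mendelian genotypes and a
#' synthetic weights table in `"genotype"` mode), raw birthweight, and
#' parental self-reported birthweights with the configured missingness. The
#' result is bit-reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `bw_trio_cohort`: list with `phenotypes` (tibble,
#'   one row per trio), `scores` (tibble of standardized scores),
#'   `genotypes` (a `bw_trio_genotypes`, genotype mode only, else `NULL`),
#'   `weights` (genotype mode only) and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_trios = 50, seed = 2))
#' nrow(coh$phenotypes)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "bw_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_trios
    covs <- simulate_covariates(n, config$covariate_params)

    genotypes <- NULL; weights <- NULL
    if (config$mode == "genotype") {
      weights <- simulate_weights(config$n_snps)
      freqs <- if (is.null(config$allele_freqs)) weights$effect_allele_freq
               else config$allele_freqs
      weights$effect_allele_freq <- freqs
      genotypes <- simulate_trio_genotypes(n, freqs, snp_ids = weights$snp_id)
      raw <- list(
        maternal_score = compute_score(genotypes$mother, weights,
                                       "weight_maternal_adj"),
        fetal_score = compute_score(genotypes$child, weights,
                                    "weight_fetal_adj"),
        paternal_score = compute_score(genotypes$father, weights,
                                       "weight_fetal_unadj")
      )
      scores <- tibble::as_tibble(lapply(raw, standardize_score))
    } else {
      rho <- config$score_correlation
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      scores <- tibble::tibble(
        maternal_score = standardize_score(z1),
        fetal_score = standardize_score(rho * z1 + sqrt(1 - rho^2) * z2),
        paternal_score = standardize_score(stats::rnorm(n))
      )
    }

    predictors <- tibble::as_tibble(c(covs, scores))
    bw <- simulate_birthweight(predictors, config)

    noise_sd <- sqrt(PARENT_BW_SD^2 - PARENT_BW_SCORE_EFFECT^2)
    maternal_own <- PARENT_BW_MEAN[["mother"]] +
      PARENT_BW_SCORE_EFFECT[["mother"]] * scores$maternal_score +
      stats::rnorm(n, 0, noise_sd[["mother"]])
    paternal_own <- PARENT_BW_MEAN[["father"]] +
      PARENT_BW_SCORE_EFFECT[["father"]] * scores$paternal_score +
      stats::rnorm(n, 0, noise_sd[["father"]])
    miss <- stats::runif(n) < config$parental_bw_missing
    maternal_own[miss] <- NA_real_; paternal_own[miss] <- NA_real_

    phenotypes <- tibble::tibble(
      trio_id = sprintf("T%04d", seq_len(n)),
      covs,
      birthweight = bw,
      maternal_own_birthweight = maternal_own,
      paternal_own_birthweight = paternal_own
    )
    structure(list(phenotypes = phenotypes,
                   scores = tibble::tibble(trio_id = phenotypes$trio_id,
                                           scores),
                   genotypes = genotypes, weights = weights, config = config),
              class = "bw_trio_cohort")
  })
}

#' @export
print.bw_trio_cohort <- function(x, ...) {
  cat("<bw_trio_cohort>\n")
  cat(sprintf("  %d trios, mode = %s, seed = %d\n",
              x$config$n_trios, x$config$mode, x$config$seed))
  cat(sprintf("  birthweight: mean %.0f g, SD %.0f g\n",
              mean(x$phenotypes$birthweight),
              stats::sd(x$phenotypes$birthweight)))
  if (!is.null(x$genotypes))
    cat(sprintf("  genotypes: %d SNPs\n", ncol(x$genotypes$mother)))
  invisible(x)
}

#' Assemble the model-ready analysis table from a cohort
#'
#' Joins phenotypes and standardized scores and, unless the cohort was
#' simulated without sex/gestational-age effects, the caller should replace
#' `birthweight_adj` by [adjust_birthweight()] output. By default
#' `birthweight_adj` is set to the raw simulated birthweight.
#'
#' @param cohort A `bw_trio_cohort`.
#' @return Tibble with one row per trio, including `birthweight_adj`.
#' @export
cohort_analysis_table <- function(cohort) {
  stopifnot(inherits(cohort, "bw_trio_cohort"))
  out <- tibble::as_tibble(c(cohort$phenotypes,
                             cohort$scores[setdiff(names(cohort$scores),
                                                   "trio_id")]))
  out$birthweight_adj <- out$birthweight
  out
}
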