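#' Configuration for the synthetic trio-cohort generator
#'
#' Bundles and validates everything the simulator needs: cohort size, SNP
#' panel, genetic-score effect sizes (g per 1 SD of the standardized score),
#' clinical effect sizes, covariate marginals, and the total birthweight SD
#' to which the Gaussian residual is calibrated.
#'
#' Two simulation modes are supported. In `"direct"` (score) mode the
#' standardized maternal/fetal scores are drawn as bivariate normal with
#' correlation `score_correlation` (paternal score independent); this is the
#' mode used for variance-calibration work because the score variance is
#' exact. In `"genotype"` mode parental genotypes are drawn under
#' Hardy-Weinberg equilibrium, child genotypes by Mendelian transmission, and
#' the scores are computed from the dosages via the score-builder functions,
#' exercising the full pipeline.
#'
#' @param n_trios Number of mother-father-child trios (default 549).
#' @param n_snps Number of score SNPs in genotype mode (default 209).
#' @param allele_freqs Optional vector of effect-allele frequencies, length
#'   `n_snps`, each strictly in (0, 1). Default: drawn by
#'   [simulate_weights()] in genotype mode.
#' @param beta_maternal_score,beta_fetal_score,beta_paternal_score Effect of
#'   each standardized genetic score on birthweight, g per 1 SD. Defaults are
#'   the full joint-model (Model 7) estimates, 60 and 57 g/SD, plus the
#'   paternal-score estimate 39 g/SD from the parental-scores model.
#' @param score_correlation Target correlation between the standardized
#'   maternal and fetal scores in direct mode (default 0; the published
#'   marginal and joint R-squared values are mutually consistent only near
#'   zero correlation of the adjusted scores).
#' @param clinical_effects Named numeric vector: g per 1 SD for continuous
#'   covariates, g per category for binary covariates. Names must appear in
#'   `covariate_params`. Default: the Model 7 clinical/anthropometric column.
#' @param covariate_params Named list of marginals as returned by
#'   [bw_cohort_marginals()].
#' @param bw_mean,total_bw_sd Marginal mean and SD of simulated birthweight
#'   in grams (defaults 3570 and 444). The residual SD is calibrated so that
#'   the marginal SD equals `total_bw_sd`.
#' @param mode `"direct"` or `"genotype"` (see above).
#' @param parental_bw_missing Fraction of trios with both parental
#'   self-reported birthweights missing (default 1 - 425/549, matching the
#'   reported additional-models subsample).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `bw_sim_config` (a validated list).
#' @seealso [simulate_cohort()], [model_generative_config()]
#' @export
#' @examples
#' cfg <- sim_config(n_trios = 100, seed = 7)
#' cfg$total_bw_sd
sim_config <- function(n_trios = 549,
                       n_snps = 209,
                       allele_freqs = NULL,
                       beta_maternal_score = 60,
                       beta_fetal_score = 57,
                       beta_paternal_score = 39,
                       score_correlation = 0,
                       clinical_effects = bw_model_effects("model7")[
                         setdiff(names(bw_model_effects("model7")),
                                 c("maternal_score", "fetal_score"))],
                       covariate_params = bw_cohort_marginals(),
                       bw_mean = 3570,
                       total_bw_sd = 444,
                       mode = c("direct", "genotype"),
                       parental_bw_missing = 1 - 425 / 549,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_trios), length(n_trios) == 1, n_trios >= 1,
            n_trios == floor(n_trios))
  stopifnot(is.numeric(n_snps), n_snps >= 1, n_snps == floor(n_snps))
  if (!is.null(allele_freqs)) {
    check_freqs(allele_freqs)
    if (length(allele_freqs) != n_snps)
      stop("allele_freqs must have length n_snps (", n_snps, ")")
  }
  if (!is.numeric(total_bw_sd) || total_bw_sd <= 0)
    stop("total_bw_sd must be a positive number of grams")
  if (abs(score_correlation) > 1)
    stop("score_correlation must lie in [-1, 1]")
  if (parental_bw_missing < 0 || parental_bw_missing > 1)
    stop("parental_bw_missing must lie in [0, 1]")
  if (length(clinical_effects)) {
    if (is.null(names(clinical_effects)) || any(names(clinical_effects) == ""))
      stop("clinical_effects must be a named numeric vector")
    missing_par <- setdiff(names(clinical_effects), names(covariate_params))
    if (length(missing_par))
      stop("no covariate_params entry for effect(s): ",
           paste(missing_par, collapse = ", "))
  }
  for (nm in names(covariate_params)) {
    p <- covariate_params[[nm]]
    if (!is.null(p$prevalence) && (p$prevalence < 0 || p$prevalence > 1))
      stop("prevalence for ", nm, " must lie in [0, 1]")
    if (!is.null(p$sd) && p$sd < 0)
      stop("sd for ", nm, " must be non-negative")
  }

  cfg <- structure(list(
    n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
    allele_freqs = allele_freqs,
    beta_maternal_score = beta_maternal_score,
    beta_fetal_score = beta_fetal_score,
    beta_paternal_score = beta_paternal_score,
    score_correlation = score_correlation,
    clinical_effects = clinical_effects,
    covariate_params = covariate_params,
    bw_mean = bw_mean, total_bw_sd = total_bw_sd,
    mode = mode, parental_bw_missing = parental_bw_missing,
    seed = as.integer(seed)
  ), class = "bw_sim_config")

  # residual variance must be non-negative under the independence default
  sv <- systematic_variance(cfg)
  if (sv > total_bw_sd^2)
    stop(sprintf(paste0("systematic variance (%.1f g^2) exceeds total_bw_sd^2 ",
                        "(%.1f g^2); variance deficit %.1f g^2"),
                 sv, total_bw_sd^2, sv - total_bw_sd^2))
  cfg
}

# Variance of the systematic part of simulated birthweight under the
# mutual-independence default: scores are standardized (variance 1, plus the
# maternal-fetal covariance term), continuous covariates contribute beta^2
# because effects are per SD, binary covariates beta^2 * p(1-p).
systematic_variance <- function(config) {
  v <- config$beta_maternal_score^2 + config$beta_fetal_score^2 +
    config$beta_paternal_score^2 +
    2 * config$score_correlation * config$beta_maternal_score *
      config$beta_fetal_score
  for (nm in names(config$clinical_effects)) {
    b <- config$clinical_effects[[nm]]
    p <- config$covariate_params[[nm]]
    v <- v + if (!is.null(p$prevalence)) b^2 * p$prevalence * (1 - p$prevalence)
             else b^2
  }
  v
}

#' Generative configuration matching one published model's architecture
#'
#' Builds a [sim_config()] whose effect sizes are exactly one model's printed
#' coefficient column (and zero for every predictor outside that model), so
#' that refitting the model on the simulated cohorts recovers the published
#' R-squared under the independence calibration.
#'
#' @param model `"model1"` ... `"model7"`.
#' @param n_trios Cohort size (default 549).
#' @param seed Integer seed.
#' @param mode Simulation mode, `"direct"` (default) or `"genotype"`.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `bw_sim_config`.
#' @export
#' @examples
#' cfg <- model_generative_config("model1", seed = 3)
#' cfg$beta_maternal_score
model_generative_config <- function(model, n_trios = 549, seed = 1L,
                                    mode = "direct", ...) {
  eff <- bw_model_effects(model)
  scores <- c("maternal_score", "fetal_score", "paternal_score")
  getb <- function(nm) if (nm %in% names(eff)) unname(eff[[nm]]) else 0
  sim_config(
    n_trios = n_trios, mode = mode,
    beta_maternal_score = getb("maternal_score"),
    beta_fetal_score = getb("fetal_score"),
    beta_paternal_score = getb("paternal_score"),
    clinical_effects = eff[setdiff(names(eff), scores)],
    seed = seed,
    ...
  )
}

check_freqs <- function(f, what = "allele frequency") {
  bad <- which(!is.finite(f) | f <= 0 | f >= 1)
  if (length(bad))
    stop(what, " out of (0,1) at SNP index ", paste(utils::head(bad, 5),
         collapse = ", "), if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}

#' @export
print.bw_sim_config <- function(x, ...) {
  cat("<bw_sim_config>\n")
  cat(sprintf("  %d trios, mode = %s, seed = %d\n", x$n_trios, x$mode, x$seed))
  cat(sprintf("  birthweight: mean %.0f g, total SD %.0f g (residual SD %.1f g)\n",
              x$bw_mean, x$total_bw_sd,
              sqrt(x$total_bw_sd^2 - systematic_variance(x))))
  cat(sprintf("  score effects (g/SD): maternal %.0f, fetal %.0f, paternal %.0f\n",
              x$beta_maternal_score, x$beta_fetal_score, x$beta_paternal_score))
  cat(sprintf("  clinical effects: %s\n",
              if (length(x$clinical_effects))
                paste(names(x$clinical_effects), round(x$clinical_effects),
                      sep = "=", collapse = ", ") else "(none)"))
  invisible(x)
}
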