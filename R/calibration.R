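#' Published marginal distributions of the study cohort
#'
#' Returns the per-covariate marginal parameters used to calibrate the trio
#' simulator: mean/SD for continuous covariates, prevalence for binary ones.
#' Values for maternal height, weight, age, gestational duration, smoking,
#' parity (primiparity) and offspring sex come from the source cohort's
#' descriptive table (n = 549 trios). Paternal height and 28-week fasting
#' glucose are not tabulated there; the defaults (177.0 (6.8) cm and
#' 4.3 (0.4) mmol/L) are typical values for a UK adult-male / healthy-pregnancy
#' population. Because all continuous effect sizes are expressed per 1 SD of
#' the covariate, the variance arithmetic downstream does not depend on these
#' two choices.
#'
#' @return Named list; each element is `list(mean=, sd=)` (continuous) or
#'   `list(prevalence=)` (binary). Units: cm, kg, years, weeks, mmol/L, g.
#' @export
#' @examples
#' bw_cohort_marginals()$maternal_height
bw_cohort_marginals <- function() {
  list(
    maternal_height  = list(mean = 165.0, sd = 6.4),
    maternal_weight  = list(mean = 76.3,  sd = 12.6),
    maternal_age     = list(mean = 30,    sd = 5),
    paternal_height  = list(mean = 177.0, sd = 6.8),
    fasting_glucose  = list(mean = 4.3,   sd = 0.4),
    gestational_age  = list(mean = 40.1,  sd = 1.2),
    smoking          = list(prevalence = 0.146),
    primiparity      = list(prevalence = 0.448),
    sex_male         = list(prevalence = 0.522)
  )
}

#' Published per-model effect sizes on birthweight
#'
#' The per-predictor coefficient columns of the seven nested birthweight
#' models, in grams per 1 SD of a continuous predictor or grams per category
#' of a binary predictor (smoking, primiparity). These are the generative
#' effect sizes the calibrated simulator uses to emulate each model's data.
#'
#' @param model One of `"model1"` ... `"model7"`.
#' @return Named numeric vector of effects (g). Score predictors are named
#'   `maternal_score`, `fetal_score`, `paternal_score` and are per 1 SD of the
#'   standardized score.
#' @export
#' @examples
#' bw_model_effects("model1")
bw_model_effects <- function(model = paste0("model", 1:7)) {
  model <- match.arg(model)
  switch(model,
    model1 = c(maternal_score = 81, fetal_score = 69),
    model2 = c(maternal_age = -38, maternal_weight = 125, smoking = -280,
               primiparity = -187, fasting_glucose = 87),
    model3 = c(maternal_age = -42, maternal_weight = 121, smoking = -273,
               primiparity = -194, fasting_glucose = 85, maternal_score = 68),
    model4 = c(maternal_age = -49, maternal_weight = 101, smoking = -251,
               primiparity = -210, fasting_glucose = 104,
               maternal_height = 52, paternal_height = 69),
    model5 = c(maternal_age = -50, maternal_weight = 97, smoking = -241,
               primiparity = -216, fasting_glucose = 106,
               maternal_height = 49, paternal_height = 66, fetal_score = 56),
    model6 = c(maternal_age = -54, maternal_weight = 97, smoking = -241,
               primiparity = -211, fasting_glucose = 104,
               maternal_height = 44, paternal_height = 61,
               maternal_score = 57, paternal_score = 39),
    model7 = c(maternal_age = -53, maternal_weight = 98, smoking = -241,
               primiparity = -217, fasting_glucose = 101,
               maternal_height = 39, paternal_height = 64,
               maternal_score = 60, fetal_score = 57)
  )
}

# Predictor lists for the seven nested models (order follows the published
# tables); binary predictors enter design matrices as raw 0/1.
bw_model_predictors <- function(model) {
  clin <- c("maternal_age", "maternal_weight", "smoking", "primiparity",
            "fasting_glucose")
  hts  <- c("maternal_height", "paternal_height")
  switch(model,
    model1 = c("maternal_score", "fetal_score"),
    model2 = clin,
    model3 = c(clin, "maternal_score"),
    model4 = c(clin, hts),
    model5 = c(clin, hts, "fetal_score"),
    model6 = c(clin, hts, "maternal_score", "paternal_score"),
    model7 = c(clin, hts, "fetal_score", "maternal_score"),
    stop("unknown model id: ", model)
  )
}

#' Binary predictors of the birthweight models
#'
#' Predictors entered as raw 0/1 indicators rather than per-SD standardized
#' columns: maternal smoking (1 = smoked) and primiparity (1 = first
#' pregnancy).
#' @return Character vector.
#' @export
bw_binary_predictors <- function() c("smoking", "primiparity")
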