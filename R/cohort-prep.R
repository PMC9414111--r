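#' Adjust birthweight for offspring sex and gestational age
#'
#' Two modes. `"internal"` (default): ordinary least squares of raw
#' birthweight on a male indicator and (gestational age - 40 weeks); the
#' adjusted value is the residual plus the fitted value at 40 weeks with sex
#' averaged over the sample, so adjusted birthweight is uncorrelated with
#' both covariates and stays on the gram scale. `"reference"`: standardize
#' against an external sex- and week-specific reference (z-score at the
#' observed completed week, rescaled to the reference distribution at 40
#' weeks for the same sex), the approach used with national birthweight
#' standards.
#'
#' @param records Tibble with `birthweight` (g), `gestational_age` (weeks,
#'   decimal) and `sex_male` (0/1).
#' @param mode `"internal"` or `"reference"`.
#' @param reference Reference table for reference mode: tibble with columns
#'   `sex` ("male"/"female"), `week` (completed weeks), `mean_g`, `sd_g`
#'   (sd_g > 0), covering every observed completed week.
#' @param quadratic Internal mode only: also remove a quadratic
#'   gestational-age term (default `FALSE`).
#' @return Numeric vector of adjusted birthweights in grams.
#' @export
#' @examples
#' rec <- tibble::tibble(birthweight = c(3300, 3600), sex_male = c(1, 0),
#'                       gestational_age = c(39, 40.5))
#' adjust_birthweight(rec)
adjust_birthweight <- function(records, mode = c("internal", "reference"),
                               reference = NULL, quadratic = FALSE) {
  mode <- match.arg(mode)
  need <- c("birthweight", "gestational_age", "sex_male")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  ga <- records$gestational_age
  if (any(!is.finite(ga) | ga <= 20 | ga >= 45))
    stop("gestational age must lie in (20, 45) weeks")

  if (mode == "reference") {
    if (is.null(reference)) stop("reference table required in reference mode")
    stopifnot(all(c("sex", "week", "mean_g", "sd_g") %in% names(reference)))
    if (any(reference$sd_g <= 0)) stop("reference sd_g must be positive")
    wk <- floor(ga)
    sex <- ifelse(records$sex_male == 1, "male", "female")
    key <- paste(sex, wk)
    refkey <- paste(reference$sex, reference$week)
    idx <- match(key, refkey)
    idx40 <- match(paste(sex, 40), refkey)
    if (anyNA(idx) || anyNA(idx40)) {
      bad <- which(is.na(idx) | is.na(idx40))
      stop("reference table does not cover record(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (sex/week ", paste(utils::head(key[bad], 5), collapse = "; "),
           ")")
    }
    z <- (records$birthweight - reference$mean_g[idx]) / reference$sd_g[idx]
    return(reference$mean_g[idx40] + z * reference$sd_g[idx40])
  }

  ga_c <- ga - 40
  df <- data.frame(bw = records$birthweight, male = records$sex_male,
                   ga_c = ga_c)
  fml <- if (quadratic) bw ~ male + ga_c + I(ga_c^2) else bw ~ male + ga_c
  fit <- stats::lm(fml, data = df)
  b <- stats::coef(fit)
  # residual + expected value at GA 40, sex averaged over the sample
  unname(stats::residuals(fit)) + b[["(Intercept)"]] +
    b[["male"]] * mean(df$male)
}

#' Filter to term births
#'
#' Retains records with gestational age in \[37, 42) weeks (closed-left,
#' open-right).
#'
#' @param records Tibble with `gestational_age`.
#' @return List: `retained` tibble, `excluded` tibble with `reason`.
#' @export
#' @examples
#' filter_term(tibble::tibble(gestational_age = c(36.9, 37, 41.9, 42)))
filter_term <- function(records) {
  ga <- records$gestational_age
  keep <- ga >= 37 & ga < 42
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- ifelse(excluded$gestational_age < 37,
                            "preterm (<37 weeks)", "post-term (>=42 weeks)")
  list(retained = records[keep, , drop = FALSE], excluded = excluded)
}

#' Filter to trios with complete data
#'
#' Retains trios for which every required phenotype field is non-missing and
#' genotypes are available for mother, father and child. Each exclusion is
#' logged with its (first applicable) reason, so log counts plus the
#' retained count always equal the input count.
#'
#' @param records Phenotype tibble with `trio_id`.
#' @param genotype_available Tibble with `trio_id` and logical `mother`,
#'   `father`, `child`; or `NULL` to skip the genotype check.
#' @param required_fields Character vector of phenotype columns that must be
#'   non-missing (may be empty).
#' @return List: `retained`, `excluded` (with `reason`), and `counts`
#'   (tibble of reason/n).
#' @export
filter_complete <- function(records, genotype_available = NULL,
                            required_fields = character()) {
  stopifnot("trio_id" %in% names(records))
  reason <- rep(NA_character_, nrow(records))
  if (!is.null(genotype_available)) {
    stopifnot(all(c("trio_id", "mother", "father", "child") %in%
                    names(genotype_available)))
    idx <- match(records$trio_id, genotype_available$trio_id)
    for (role in c("mother", "father", "child")) {
      ok <- genotype_available[[role]][idx]
      ok[is.na(ok)] <- FALSE
      miss <- is.na(reason) & !ok
      reason[miss] <- paste0("missing ", role, " genotype")
    }
  }
  for (f in required_fields) {
    if (!f %in% names(records))
      stop("required field not in records: ", f)
    miss <- is.na(reason) & is.na(records[[f]])
    reason[miss] <- paste0("missing ", f)
  }
  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  tab <- table(reason[!keep])
  counts <- tibble::tibble(reason = names(tab), n = as.integer(tab))
  list(retained = records[keep, , drop = FALSE], excluded = excluded,
       counts = counts)
}

#' Compare included and excluded participants
#'
#' Two-sample t-tests for continuous variables (Welch by default, pooled
#' variance optional) and chi-square tests on the 2 x k contingency table for
#' categorical variables (no continuity correction by default). A variable
#' with an empty group is reported as not testable rather than erroring.
#'
#' @param included,excluded Tibbles with the variables to compare.
#' @param continuous,categorical Character vectors of column names.
#' @param var_equal Use the pooled-variance t-test (default `FALSE` = Welch).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return Tibble: `variable`, `type`, `statistic`, `df`, `p`, `testable`.
#' @export
compare_cohorts <- function(included, excluded,
                            continuous = character(),
                            categorical = character(),
                            var_equal = FALSE, correct = FALSE) {
  one <- function(var, type) {
    x <- included[[var]]; y <- excluded[[var]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0)
      return(tibble::tibble(variable = var, type = type,
                            statistic = NA_real_, df = NA_real_,
                            p = NA_real_, testable = FALSE))
    if (type == "continuous") {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      tibble::tibble(variable = var, type = type,
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value,
                     testable = TRUE)
    } else {
      lev <- sort(unique(c(x, y)))
      tab <- rbind(table(factor(x, levels = lev)),
                   table(factor(y, levels = lev)))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      tibble::tibble(variable = var, type = type,
                     statistic = unname(ct$statistic),
                     df = unname(ct$parameter), p = ct$p.value,
                     testable = TRUE)
    }
  }
  rows <- c(lapply(continuous, one, type = "continuous"),
            lapply(categorical, one, type = "categorical"))
  do.call(rbind, rows)
}

#' Prepare the analysis cohort end to end
#'
#' Applies, in order: term-birth filter, completeness filter, and sex/GA
#' adjustment of birthweight (added as `birthweight_adj`). Returns the
#' retained analysis table plus the combined exclusion log.
#'
#' @inheritParams adjust_birthweight
#' @inheritParams filter_complete
#' @return List: `cohort` (tibble with `birthweight_adj`), `exclusions`
#'   (tibble with `reason`), `comparison` (included-vs-excluded table, or
#'   `NULL` if nothing was excluded).
#' @export
prepare_cohort <- function(records, genotype_available = NULL,
                           required_fields = character(),
                           mode = "internal", reference = NULL) {
  term <- filter_term(records)
  comp <- filter_complete(term$retained, genotype_available, required_fields)
  keep_cols <- intersect(names(records), names(term$excluded))
  exclusions <- rbind(term$excluded[, c(keep_cols, "reason")],
                      comp$excluded[, c(keep_cols, "reason")])
  cohort <- comp$retained
  cohort$birthweight_adj <- adjust_birthweight(cohort, mode = mode,
                                               reference = reference)
  comparison <- NULL
  if (nrow(exclusions) > 0) {
    cont <- intersect(c("maternal_height", "maternal_weight",
                        "gestational_age", "birthweight", "maternal_age"),
                      names(records))
    cat_ <- intersect(c("smoking", "primiparity", "sex_male"),
                      names(records))
    comparison <- compare_cohorts(cohort, exclusions,
                                  continuous = cont, categorical = cat_)
  }
  list(cohort = cohort, exclusions = exclusions, comparison = comparison)
}
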