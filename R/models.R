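# Nested linear models of adjusted birthweight with per-SD coefficient
# reporting, nested F-tests, VIF and residual diagnostics.

#' Fit one birthweight model with per-SD coefficient reporting
#'
#' Ordinary least squares of the outcome on the listed predictors.
#' Continuous predictors are standardized (centered, divided by the n-1
#' sample SD) before fitting, so their coefficients read as grams per 1 SD;
#' binary predictors enter as raw 0/1 and read as grams per category.
#' Standard errors come from the classical OLS covariance estimator and 95%
#' CIs use the t distribution with residual degrees of freedom.
#'
#' @param data Tibble containing `outcome` and all predictors.
#' @param predictors Character vector of predictor columns (order is the
#'   reporting order).
#' @param outcome Outcome column name (default `"birthweight_adj"`, grams).
#' @param binary Which predictors are binary indicators (default
#'   [bw_binary_predictors()] intersected with `predictors`).
#' @param model_id Optional label stored on the fit.
#' @param scale_stats Optional precomputed list of `center`/`scale` named
#'   vectors used to standardize continuous predictors (used by the
#'   bootstrap so resamples reuse the full-sample SDs).
#' @param level CI level (default 0.95).
#' @return Object of class `bw_model_fit`: `coefficients` tibble (term,
#'   estimate, se, t, p, ci_lower, ci_upper), `r2`, `adj_r2`, `rss`, `n`,
#'   `df_resid`, `n_predictors`, `predictors`, `binary`, `outcome`,
#'   `model_id`, `scale_stats`, and the underlying `lm` fit.
#' @export
#' @examples
#' coh <- cohort_analysis_table(simulate_cohort(sim_config(n_trios = 200,
#'                                                         seed = 1)))
#' fit_bw_model(coh, c("maternal_score", "fetal_score"))
fit_bw_model <- function(data, predictors, outcome = "birthweight_adj",
                         binary = intersect(bw_binary_predictors(),
                                            predictors),
                         model_id = NULL, scale_stats = NULL, level = 0.95) {
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols))
    stop("data missing column(s): ", paste(missing_cols, collapse = ", "))
  cont <- setdiff(predictors, binary)
  keep <- stats::complete.cases(data[, c(outcome, predictors), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1)
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")

  if (is.null(scale_stats)) {
    scale_stats <- list(
      center = vapply(data[cont], mean, numeric(1)),
      scale = vapply(data[cont], stats::sd, numeric(1))
    )
  }
  zero <- names(scale_stats$scale)[scale_stats$scale == 0]
  if (length(zero))
    stop("constant continuous predictor(s): ", paste(zero, collapse = ", "))

  X <- as.data.frame(data[, predictors, drop = FALSE])
  for (nm in cont)
    X[[nm]] <- (X[[nm]] - scale_stats$center[[nm]]) / scale_stats$scale[[nm]]
  X$.outcome <- data[[outcome]]

  if (p > 0) {
    mm <- stats::model.matrix(~ ., data = X[, predictors, drop = FALSE])
    qrx <- qr(mm)
    if (qrx$rank < ncol(mm)) {
      dropped <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
      stop("design is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
  }
  fml <- stats::as.formula(paste(".outcome ~",
                                 if (p == 0) "1" else
                                 paste(sprintf("`%s`", predictors),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = X)
  sm <- summary(fit)
  cf <- sm$coefficients
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  coef_tab <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    t = cf[, "t value"],
    p = cf[, "Pr(>|t|)"],
    ci_lower = cf[, "Estimate"] - tcrit * cf[, "Std. Error"],
    ci_upper = cf[, "Estimate"] + tcrit * cf[, "Std. Error"]
  )
  coef_tab$term <- gsub("`", "", coef_tab$term)
  r2 <- sm$r.squared
  structure(list(
    coefficients = coef_tab,
    r2 = r2,
    adj_r2 = adjusted_r2(r2, n, p),
    rss = sum(stats::residuals(fit)^2),
    n = n, df_resid = fit$df.residual, n_predictors = p,
    predictors = predictors, binary = binary, outcome = outcome,
    model_id = model_id, scale_stats = scale_stats, level = level,
    lm = fit
  ), class = "bw_model_fit")
}

#' @export
print.bw_model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<bw_model_fit%s> n = %d, R2 = %.3f, Adj-R2 = %.3f\n",
              if (!is.null(x$model_id)) paste0(": ", x$model_id) else "",
              x$n, x$r2, x$adj_r2))
  print(as.data.frame(lapply(x$coefficients, function(v)
    if (is.numeric(v)) signif(v, digits) else v)), row.names = FALSE)
  invisible(x)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`, the penalized fit statistic used to
#' judge whether added predictors improve a model.
#'
#' @param r2 R-squared in \[0, 1\].
#' @param n Sample size.
#' @param p Number of non-intercept predictors.
#' @return Adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2(0.217, 549, 5)
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R-squared requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' F-test comparing two nested model fits
#'
#' `F = ((RSS_r - RSS_f)/df1) / (RSS_f/df2)` with `df1` the number of added
#' predictors and `df2` the full model's residual df; the p-value is the
#' upper tail of the F distribution.
#'
#' @param fit_reduced,fit_full `bw_model_fit`s on the same outcome and
#'   observations, the reduced model's predictors a strict subset of the
#'   full model's.
#' @return Tibble: `reduced`, `full`, `F`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "bw_model_fit"),
            inherits(fit_full, "bw_model_fit"))
  if (fit_reduced$n != fit_full$n || fit_reduced$outcome != fit_full$outcome)
    stop("fits must share outcome and observations")
  if (!all(fit_reduced$predictors %in% fit_full$predictors) ||
      fit_full$n_predictors <= fit_reduced$n_predictors)
    stop("models are not strictly nested")
  df1 <- fit_full$n_predictors - fit_reduced$n_predictors
  df2 <- fit_full$df_resid
  f <- ((fit_reduced$rss - fit_full$rss) / df1) / (fit_full$rss / df2)
  f <- max(f, 0)  # guard tiny negative rounding
  tibble::tibble(
    reduced = fit_reduced$model_id %||% "reduced",
    full = fit_full$model_id %||% "full",
    F = f, df1 = df1, df2 = df2,
    p = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' (on the same transformed scale as the fit) on all other predictors with
#' an intercept. Perfect collinearity is reported as `Inf` together with the
#' most correlated partner.
#'
#' @param fit A `bw_model_fit` with at least two predictors.
#' @return Tibble: `term`, `vif`, `note`.
#' @export
vif_values <- function(fit) {
  stopifnot(inherits(fit, "bw_model_fit"))
  X <- stats::model.matrix(fit$lm)[, -1, drop = FALSE]
  if (ncol(X) < 2) stop("VIF requires at least 2 non-intercept predictors")
  out <- lapply(seq_len(ncol(X)), function(j) {
    r2j <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2j > 1 - 1e-12) {
      partner <- colnames(X)[-j][which.max(abs(stats::cor(
        X[, -j, drop = FALSE], X[, j])))]
      tibble::tibble(term = colnames(X)[j], vif = Inf,
                     note = paste0("perfectly collinear with ", partner))
    } else {
      tibble::tibble(term = colnames(X)[j], vif = 1 / (1 - r2j),
                     note = "")
    }
  })
  res <- do.call(rbind, out)
  res$term <- gsub("`", "", res$term)
  res
}

#' Residual diagnostics for a fitted model
#'
#' Returns the residual/fitted pairs for plotting plus two summaries: the
#' residual skewness and the slope of |residual| on fitted values (a simple
#' heteroscedasticity indicator). No hypothesis test is enforced.
#'
#' @param fit A `bw_model_fit`.
#' @return List: `data` (tibble `fitted`, `residual`), `skewness`,
#'   `abs_resid_slope`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "bw_model_fit"))
  r <- stats::residuals(fit$lm)
  f <- stats::fitted(fit$lm)
  skew <- mean((r - mean(r))^3) / stats::sd(r)^3
  slope <- unname(stats::coef(stats::lm(abs(r) ~ f))[2])
  list(data = tibble::tibble(fitted = f, residual = r),
       skewness = skew, abs_resid_slope = slope)
}
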