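#' Fit the full ladder of nested birthweight models
#'
#' Fits Models 1-7 on the prepared analysis table, computes the reported
#' nested comparisons (3 vs 2, 4 vs 2, 5 vs 4, 6 vs 4, 7 vs 4), bootstrap
#' percentile CIs for each model's R-squared, and VIFs. Models whose
#' required variables are missing are skipped with a logged reason; the
#' others still run. If both parental self-reported birthweights are
#' present, the additional parental-birthweight models are fitted on the
#' complete subsample: heights model plus parents' own birthweights, with
#' and without the fetal score.
#'
#' The model ladder (outcome: sex/GA-adjusted birthweight, g):
#' \describe{
#'   \item{model1}{maternal + fetal genetic scores}
#'   \item{model2}{maternal age, weight, smoking, parity, fasting glucose}
#'   \item{model3}{model2 + maternal score}
#'   \item{model4}{model2 + maternal and paternal heights}
#'   \item{model5}{model4 + fetal score}
#'   \item{model6}{model4 + maternal + paternal scores}
#'   \item{model7}{model4 + fetal + maternal scores}
#' }
#'
#' @param data Analysis tibble (see [cohort_analysis_table()] /
#'   [prepare_cohort()]) with `birthweight_adj`, the clinical columns and
#'   standardized score columns.
#' @param outcome Outcome column (default `"birthweight_adj"`).
#' @param n_boot Bootstrap resamples per model (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Integer seed for the bootstrap streams.
#' @param parental_bw Fit the additional parental-birthweight models when
#'   the columns exist (default `TRUE`).
#' @return Object of class `bw_model_suite`: `fits` (named list of
#'   `bw_model_fit`), `nested` (tibble of F-tests), `bootstrap` (tibble),
#'   `vif` (tibble), `skipped` (tibble of model/reason), `extra` (parental
#'   birthweight fits or `NULL`), `seed`.
#' @export
run_model_suite <- function(data, outcome = "birthweight_adj",
                            n_boot = 1000, level = 0.95, seed = 1L,
                            parental_bw = TRUE) {
  models <- paste0("model", 1:7)
  fits <- list()
  skipped <- tibble::tibble(model = character(), reason = character())
  for (m in models) {
    preds <- bw_model_predictors(m)
    absent <- setdiff(c(outcome, preds), names(data))
    absent <- c(absent,
                preds[vapply(intersect(preds, names(data)),
                             function(nm) all(is.na(data[[nm]])), TRUE)])
    if (length(absent)) {
      skipped <- rbind(skipped, tibble::tibble(
        model = m,
        reason = paste("missing variable(s):",
                       paste(unique(absent), collapse = ", "))))
      next
    }
    fits[[m]] <- fit_bw_model(data, preds, outcome = outcome,
                              model_id = m, level = level)
  }

  pairs <- list(c("model2", "model3"), c("model2", "model4"),
                c("model4", "model5"), c("model4", "model6"),
                c("model4", "model7"))
  nested <- do.call(rbind, lapply(pairs, function(pr) {
    if (all(pr %in% names(fits))) {
      tst <- nested_f_test(fits[[pr[1]]], fits[[pr[2]]])
      # sanity: R-squared can never decrease when predictors are added
      stopifnot(fits[[pr[2]]]$r2 >= fits[[pr[1]]]$r2 - 1e-12)
      tst
    } else NULL
  }))

  boot <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ci <- bootstrap_r2(data, f$predictors, outcome = outcome,
                       n_boot = n_boot, level = level,
                       seed = seed + i)
    tibble::tibble(model = f$model_id, statistic = "r2",
                   estimate = ci$estimate, lower = ci$lower,
                   upper = ci$upper, level = level, n_boot = n_boot,
                   seed = ci$seed)
  }))

  vif_tab <- do.call(rbind, lapply(fits, function(f) {
    if (f$n_predictors < 2) return(NULL)
    v <- vif_values(f)
    v$model <- f$model_id
    v[, c("model", "term", "vif", "note")]
  }))

  extra <- NULL
  pb_cols <- c("maternal_own_birthweight", "paternal_own_birthweight")
  if (parental_bw && all(pb_cols %in% names(data)) &&
      any(stats::complete.cases(data[, pb_cols]))) {
    base4 <- bw_model_predictors("model4")
    sub <- data[stats::complete.cases(data[, c(outcome, base4, pb_cols)]), ]
    if (nrow(sub) > length(base4) + 4) {
      extra <- list(
        parental_bw = fit_bw_model(sub, c(base4, pb_cols),
                                   outcome = outcome,
                                   model_id = "parental_bw", level = level),
        parental_bw_fetal = if ("fetal_score" %in% names(sub) &&
                                !all(is.na(sub$fetal_score)))
          fit_bw_model(sub, c(base4, pb_cols, "fetal_score"),
                       outcome = outcome,
                       model_id = "parental_bw_fetal", level = level)
      )
    }
  }

  structure(list(fits = fits, nested = nested, bootstrap = boot,
                 vif = vif_tab, skipped = skipped, extra = extra,
                 outcome = outcome, seed = seed, n = fits[[1]]$n %||%
                   nrow(data)),
            class = "bw_model_suite")
}

#' @export
print.bw_model_suite <- function(x, ...) {
  cat("<bw_model_suite>\n")
  for (f in x$fits)
    cat(sprintf("  %-7s n = %d  R2 = %.3f  Adj-R2 = %.3f\n",
                f$model_id, f$n, f$r2, f$adj_r2))
  if (nrow(x$skipped))
    cat("  skipped:", paste(x$skipped$model, collapse = ", "), "\n")
  if (!is.null(x$nested)) {
    cat("  nested F-tests:\n")
    for (i in seq_len(nrow(x$nested)))
      cat(sprintf("    %s vs %s: F = %.2f (df %d, %d), p = %.3g\n",
                  x$nested$full[i], x$nested$reduced[i], x$nested$F[i],
                  x$nested$df1[i], x$nested$df2[i], x$nested$p[i]))
  }
  invisible(x)
}

#' R-squared-with-CI series across the model ladder
#'
#' One row per fitted model: the R-squared point estimate and its bootstrap
#' percentile interval, the data series behind the models-summary figure.
#'
#' @param suite A `bw_model_suite`.
#' @return Tibble: `model`, `r2`, `adj_r2`, `lower`, `upper`.
#' @export
fig_r2_series <- function(suite) {
  stopifnot(inherits(suite, "bw_model_suite"))
  out <- suite$bootstrap[, c("model", "estimate", "lower", "upper")]
  names(out)[2] <- "r2"
  out$adj_r2 <- vapply(out$model, function(m) suite$fits[[m]]$adj_r2,
                       numeric(1))
  out[, c("model", "r2", "adj_r2", "lower", "upper")]
}

#' Write the per-model coefficient report
#'
#' Emits a TSV mirroring the published table layout: per model and term, the
#' change in birthweight (g) per 1 SD (continuous) or per category (binary),
#' the 95% CI, t and p, plus caption fields (R-squared, Adj-R-squared, n).
#'
#' @param suite A `bw_model_suite`.
#' @param path Output TSV path.
#' @return The report tibble, invisibly.
#' @export
write_model_report <- function(suite, path) {
  stopifnot(inherits(suite, "bw_model_suite"))
  all_fits <- c(suite$fits,
                Filter(Negate(is.null), suite$extra %||% list()))
  rows <- do.call(rbind, lapply(all_fits, function(f) {
    cf <- f$coefficients
    tibble::tibble(model = f$model_id, term = cf$term,
                   estimate_g = cf$estimate, ci_lower = cf$ci_lower,
                   ci_upper = cf$ci_upper, t = cf$t, p = cf$p,
                   r2 = f$r2, adj_r2 = f$adj_r2, n = f$n)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}

#' Serialize a suite run to a JSON summary
#'
#' Records every number the rendered reports need (fits, nested tests,
#' bootstrap intervals, VIF, skipped models, seed), so reports can be
#' regenerated without recomputation.
#'
#' @param suite A `bw_model_suite`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_suite_summary <- function(suite, path) {
  stopifnot(inherits(suite, "bw_model_suite"))
  fits <- lapply(suite$fits, function(f) list(
    model = f$model_id, n = f$n, r2 = f$r2, adj_r2 = f$adj_r2,
    rss = f$rss, coefficients = f$coefficients))
  out <- list(seed = suite$seed, outcome = suite$outcome,
              fits = fits, nested = suite$nested,
              bootstrap = suite$bootstrap, vif = suite$vif,
              skipped = suite$skipped)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
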