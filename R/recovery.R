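#' Monte-Carlo parameter recovery for a published model architecture
#'
#' Repeatedly simulates a cohort from one model's generative configuration
#' (printed effect column, published marginals, independence, residual SD
#' calibrated to the total birthweight SD) and refits that model, recording
#' R-squared, adjusted R-squared and the fitted coefficients per replicate.
#' For the two-score model the marginal single-score regressions are also
#' fitted, since their variance-explained values are reported separately.
#'
#' @param model `"model1"` ... `"model7"`.
#' @param n_reps Number of replicates (default 200).
#' @param n_trios Cohort size per replicate (default 549).
#' @param seed Integer base seed; replicate r uses `seed + r`.
#' @param marginals Also fit each single-score regression (only meaningful
#'   for `"model1"`; default `model == "model1"`).
#' @return Tibble with one row per replicate: `rep`, `r2`, `adj_r2`, one
#'   `coef_<term>` column per predictor, and (with `marginals`)
#'   `r2_maternal_only`, `r2_fetal_only`.
#' @export
#' @examples
#' rec <- run_recovery("model1", n_reps = 5, n_trios = 200, seed = 1)
#' colMeans(rec[, c("r2", "coef_maternal_score")])
run_recovery <- function(model, n_reps = 200, n_trios = 549, seed = 1L,
                         marginals = identical(model, "model1")) {
  preds <- bw_model_predictors(model)
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- model_generative_config(model, n_trios = n_trios,
                                   seed = seed + r)
    coh <- simulate_cohort(cfg)
    # generative configs carry no sex/GA effect, so the simulated
    # birthweight is already on the adjusted scale
    dat <- cohort_analysis_table(coh)
    fit <- fit_bw_model(dat, preds, model_id = model)
    cf <- fit$coefficients
    est <- cf$estimate[match(preds, cf$term)]
    names(est) <- paste0("coef_", preds)
    out <- c(rep = r, r2 = fit$r2, adj_r2 = fit$adj_r2, est)
    if (marginals) {
      for (sc in intersect(c("maternal_score", "fetal_score"), preds)) {
        f1 <- fit_bw_model(dat, sc)
        out[[paste0("r2_", sub("_score", "_only", sc))]] <- f1$r2
      }
    }
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Summarize a recovery run
#'
#' Column means of [run_recovery()] output (dropping the replicate index),
#' i.e. the Monte-Carlo estimates of the expected fitted statistics at the
#' study's sample size.
#'
#' @param recovery Output of [run_recovery()].
#' @return Named numeric vector of means.
#' @export
recovery_summary <- function(recovery) {
  colMeans(recovery[, setdiff(names(recovery), "rep"), drop = FALSE])
}
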