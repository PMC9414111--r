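#' Bootstrap confidence interval for a model's R-squared
#'
#' Nonparametric case resampling: trios are resampled with replacement, the
#' model refitted on each resample, and the percentile interval of the
#' resampled statistic reported. Continuous predictors are standardized once
#' with the full-sample SDs (not per resample), so resampled coefficients
#' stay on a common scale. Rank-deficient resamples are redrawn (capped
#' retries), which can only occur for near-degenerate designs.
#'
#' @inheritParams fit_bw_model
#' @param statistic `"r2"` (default) or `"adj_r2"`.
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param level Interval level in (0, 1) (default 0.95).
#' @param seed Integer seed; results are deterministic given it.
#' @param max_retries Redraw budget for degenerate resamples (default 100).
#' @return Object of class `bw_bootstrap_ci`: `statistic`, `estimate`
#'   (full-sample value), `lower`, `upper`, `level`, `n_boot`, `seed`,
#'   `replicates` (numeric vector).
#' @export
#' @examples
#' coh <- cohort_analysis_table(simulate_cohort(sim_config(n_trios = 150,
#'                                                         seed = 4)))
#' bootstrap_r2(coh, c("maternal_score", "fetal_score"), n_boot = 100,
#'              seed = 9)
bootstrap_r2 <- function(data, predictors, outcome = "birthweight_adj",
                         binary = intersect(bw_binary_predictors(),
                                            predictors),
                         statistic = c("r2", "adj_r2"),
                         n_boot = 1000, level = 0.95, seed = 1L,
                         max_retries = 100) {
  statistic <- match.arg(statistic)
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")

  full <- fit_bw_model(data, predictors, outcome = outcome, binary = binary)
  cont <- setdiff(predictors, binary)
  keep <- stats::complete.cases(data[, c(outcome, predictors), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  # pre-transform once with full-sample stats; resamples fit the raw design
  X <- as.matrix(d[, predictors, drop = FALSE])
  for (nm in cont)
    X[, nm] <- (X[, nm] - full$scale_stats$center[[nm]]) /
      full$scale_stats$scale[[nm]]
  X <- cbind(`(Intercept)` = 1, X)
  y <- d[[outcome]]
  n <- length(y)
  p <- length(predictors)

  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (try in seq_len(max_retries + 1)) {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (qr(Xb)$rank == ncol(Xb)) {
          yb <- y[idx]
          fitb <- stats::lm.fit(Xb, yb)
          rss <- sum(fitb$residuals^2)
          tss <- sum((yb - mean(yb))^2)
          r2b <- 1 - rss / tss
          return(if (statistic == "r2") r2b else adjusted_r2(r2b, n, p))
        }
      }
      stop("could not draw a full-rank bootstrap resample after ",
           max_retries, " retries")
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(
    statistic = statistic,
    estimate = if (statistic == "r2") full$r2 else full$adj_r2,
    lower = qs[1], upper = qs[2], level = level,
    n_boot = n_boot, seed = seed, replicates = reps
  ), class = "bw_bootstrap_ci")
}

#' @export
print.bw_bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bw_bootstrap_ci> %s = %.4f, %d%% percentile CI [%.4f, %.4f] (B = %d, seed = %d)\n",
              x$statistic, x$estimate, round(100 * x$level), x$lower,
              x$upper, x$n_boot, x$seed))
  invisible(x)
}
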