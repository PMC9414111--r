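# Shared fixtures, built in code at test time.

# Small direct-mode cohort analysis table
toy_analysis_table <- function(n = 200, seed = 1, ...) {
  cohort_analysis_table(simulate_cohort(sim_config(n_trios = n, seed = seed,
                                                   ...)))
}

# Hand-written 5-variant weights table exercising both filter predicates
toy_filter_weights <- function() {
  tibble::tibble(
    snp_id = paste0("rs", 1:5),
    chrom = "1", pos = 1:5 * 100L,
    effect_allele = c("A", "C", "G", "T", "A"),
    other_allele = c("G", "T", "A", "C", "C"),
    effect_allele_freq = c(0.0005, 0.002, 0.3, 0.4, 0.0009),
    imputation_r2 = c(0.9, 0.3, 0.9, 0.5, 0.9),
    weight_maternal_adj = 1:5,
    weight_fetal_adj = 1:5 / 10,
    weight_fetal_unadj = 1:5 / 100
  )
}

# Independent normal-equations oracle for OLS (no lm)
normal_equations_fit <- function(X, y) {
  Xi <- cbind(1, X)
  beta <- solve(crossprod(Xi), crossprod(Xi, y))
  resid <- y - Xi %*% beta
  list(coef = drop(beta), rss = sum(resid^2),
       r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
}
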