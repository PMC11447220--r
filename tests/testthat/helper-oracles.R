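# Independent oracles used to check the statistical routines. These are
# deliberately brute-force / closed-form and share no code with the package.

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins: sum of hypergeometric probabilities not exceeding the
# observed table's probability (relative tolerance for ties).
fisher_enum_p <- function(tab, rel_tol = 1e-7) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + rel_tol)])
}

# Monte-Carlo permutation p for the trend in a 2 x k table: the conditional
# (margin-fixed) null is sampled with r2dtable and the linear trend
# statistic sum(s_i * x_1i) is compared two-sidedly around its null mean.
# Ties at the observed value count half (mid-p): the permutation statistic
# lives on a lattice, and half-tie counting is the standard estimator of the
# tail mass a continuous (normal) reference distribution assigns.
trend_permutation_p <- function(tab, scores, draws = 1e5) {
  n_i <- colSums(tab); R1 <- sum(tab[1, ]); N <- sum(tab)
  t_obs <- sum(scores * tab[1, ])
  t_null <- R1 / N * sum(n_i * scores)
  sims <- r2dtable(draws, c(R1, N - R1), n_i)
  t_sim <- vapply(sims, function(m) sum(scores * m[1, ]), 0)
  d_obs <- abs(t_obs - t_null); d_sim <- abs(t_sim - t_null)
  mean(d_sim > d_obs + 1e-9) + 0.5 * mean(abs(d_sim - d_obs) <= 1e-9)
}

# small quick simulation config shared across tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples_per_cohort = 150L, n_cohorts = 2L, n_genes_total = 200L,
         n_pathway_genes = 30L, seed = 11L),
    list(...))
  do.call(simulation_config, args)
}

# full harmonization stack: rank -> impute -> reference-batch correct
harmonize <- function(cohort, reference = "TCGA_SYN") {
  combat_correct(impute_missing(dense_rank_normalize(cohort$expression)),
                 reference)$matrix
}
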