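#!/usr/bin/env Rscript
# Stage 4: association analyses on the scored held-out cohort.
#
# Runs the validation suite: pooled and ER-stratified Fisher tests of pCR
# vs phenocopy call, Cochran-Armitage trend over RCB classes and over the
# longitudinal timepoints, phenocopy-rate summaries, per-drug sensitivity
# linear models (phenocopy score + genotype), and the covariate-adjusted
# pCR logistic model. One results_*.tsv per analysis under results/.
#
# Usage: Rscript analysis/04_validate.R   (after 03_score.R)

suppressMessages(library(tp53phenocopy))
cfg <- load_config("results/config.yaml")

res <- run_validate(cfg, file.path(cfg$out_dir, "scores.tsv"))

pooled <- res$pcr_fisher[res$pcr_fisher$model == "pcr_pooled", ]
cat(sprintf("pCR vs phenocopy (pooled): Fisher p = %.2e, pCR odds ratio = %.2f, n = %d\n",
            pooled$p, 1 / pooled$odds_ratio, pooled$n))
cat(sprintf("RCB trend over classes 0-III: z = %.2f, p = %.2e\n",
            res$rcb_trend$stat, res$rcb_trend$p))
tp <- res$timepoint_rates
cat(sprintf("phenocopy proportion pre -> on -> post: %.1f%% -> %.1f%% -> %.1f%% (trend p = %.2e)\n",
            100 * tp$proportion[tp$stratum == "pre"],
            100 * tp$proportion[tp$stratum == "on"],
            100 * tp$proportion[tp$stratum == "post"],
            res$timepoint_trend$p))
dm <- res$drug_models[res$drug_models$covariate == "phenocopy", ]
cat(sprintf("drug models: phenocopy coefficient %.2f to %.2f (negative = more sensitive), %d/%d at p < 0.05\n",
            min(dm$coef), max(dm$coef), sum(dm$p < 0.05), nrow(dm)))
if (!is.null(res$pcr_adjusted)) {
  i <- res$pcr_adjusted$covariate == "phenocopy"
  cat(sprintf("adjusted pCR model: phenocopy log-OR %.2f (p = %.2e), grade/T/N adjusted\n",
              res$pcr_adjusted$coef[i], res$pcr_adjusted$p[i]))
}
cat("results tables written under results/\n")
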