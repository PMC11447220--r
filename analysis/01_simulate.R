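#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-cohort study.
#
# Builds a two-cohort dataset with the planted genotype -> phenotype ->
# response structure: a 2000-sample pan-cancer reference cohort (the
# training set, playing the TCGA role) and a 1000-sample held-out cohort
# with batch effects, plus mutation/copy-number calls, clinical annotation
# (pCR, ER status, RCB class, longitudinal timepoints) and drug-response
# tables. Hidden truth goes to truth.tsv, which later stages never read.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(tp53phenocopy))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- pipeline_config(
  fixture_dir = "results/fixture", out_dir = "results",
  simulation = list(n_samples_per_cohort = c(2000L, 1000L), n_cohorts = 2L),
  seed = seed)
save_config(cfg, "results/config.yaml")

manifest <- run_simulate(cfg)
truth <- utils::read.delim(manifest[["truth"]])

cat(sprintf("simulated %d samples in %d cohorts (seed %d)\n",
            nrow(truth), length(unique(truth$cohort)), seed))
cat(sprintf("  genotype TP53 loss: %.1f%%  |  phenotype-positive: %.1f%%\n",
            100 * mean(truth$genotype_loss),
            100 * mean(truth$phenotype_positive)))
cat(sprintf("  phenocopies without the genotype: %.1f%% of non-genotype samples\n",
            100 * mean(truth$phenotype_positive[!truth$genotype_loss])))
cat("fixture written to results/fixture/\n")
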