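#!/usr/bin/env Rscript
# Stage 3: apply the locked model, unmodified, to the held-out cohort.
#
# The held-out cohort is harmonized against the reference batch exactly as
# in training and scored with the locked booster; no refitting happens
# here. Calls go to results/scores.tsv. Evaluation against the generator's
# hidden truth is reported for the narrative only.
#
# Usage: Rscript analysis/03_score.R   (after 02_train.R)

suppressMessages(library(tp53phenocopy))
cfg <- load_config("results/config.yaml")

calls <- run_score(cfg, file.path(cfg$out_dir, "model.json"))
truth <- utils::read.delim(file.path(cfg$fixture_dir, "truth.tsv"))
m <- match(calls$sample, truth$sample)

cat(sprintf("scored %d held-out samples; %.1f%% called phenocopy\n",
            nrow(calls), 100 * mean(calls$phenocopy)))
cat(sprintf("held-out AUC vs hidden phenotype state: %.3f\n",
            auc_score(truth$phenotype_positive[m], calls$score)))
cat(sprintf("phenocopy call rate | genotype loss: %.1f%%  | no genotype loss: %.1f%%\n",
            100 * mean(calls$phenocopy[truth$genotype_loss[m]]),
            100 * mean(calls$phenocopy[!truth$genotype_loss[m]])))
pw <- truth$phenotype_positive[m] & !truth$genotype_loss[m]
cat(sprintf("true phenocopies without the genotype called positive: %.1f%% (n = %d)\n",
            100 * mean(calls$phenocopy[pw]), sum(pw)))
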