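---
title: "The TP53-loss phenocopy workflow: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TP53-loss phenocopy workflow: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tp53phenocopy)
```

## The problem

p53 is the most commonly inactivated tumor suppressor, and its loss changes
how tumors respond to DNA-damaging chemotherapy. DNA sequencing alone is a
blunt instrument for p53 status: many mutations are mono-allelic or
non-functional, while other tumors silence the pathway without any TP53
mutation at all — through MDM2 amplification, epigenetic changes, or
upstream lesions. Such tumors *phenocopy* TP53 loss: their transcriptome
looks like that of a biallelically inactivated tumor even though their
genotype does not.

This package implements a workflow that (i) defines a high-confidence
*genotype* of biallelic TP53 loss from mutation and copy-number tables,
(ii) trains an expression-only classifier on that genotype restricted to a
p53/cell-cycle pathway gene set, and (iii) uses the resulting *phenocopy
call* — rather than the genotype — as the predictor in downstream
chemotherapy-response analyses. Because the real cohorts behind such
analyses are large external resources, the package also ships a synthetic
multi-cohort generator with a planted causal structure, so that every stage
can be validated offline against known truth.

## The genotype label

A sample is labelled `dual_loss` when it carries **two coding TP53
mutations**, or **one coding mutation plus TP53 copy-number loss**. Coding
status comes from a declared MAF `Variant_Classification` vocabulary
(missense, nonsense, frameshift, splice, in-frame indel, nonstop,
translation-start; `Silent` and UTR/flank/intron classes never count).
Copy-number loss is scheme-specific, mirroring how public resources are
thresholded:

| scheme | rule | typical use |
|---|---|---|
| `gistic_le_minus1` | GISTIC value ≤ −1 | pan-cancer tumor cohorts |
| `gistic_lt_minus1` | GISTIC value < −1 | cell-line panels with noisier shallow losses |
| `log2_lt_minus1` | log2 CN ratio < −1 | continuous copy-number data |

MDM2 degrades wild-type p53, so MDM2 alteration (amplification, optionally
any coding MDM2 mutation) is treated as functionally equivalent: by default
`mdm2_altered` alone sets the training label `tp53_loss = TRUE`. Whether
mutation should count in addition to amplification is genuinely
underdetermined, so both behaviors are exposed
(`mdm2_rule = "amplification_or_mutation" | "amplification_only" | "ignore"`,
`mdm2_sufficient = TRUE/FALSE`). Identical duplicate mutation records are
collapsed before counting; conflicting duplicate copy-number records are an
error rather than a silent pick.

## Expression harmonization

The classifier must score data from many platforms, so the working scale is
deliberately crude but transferable:

1. **Dense ranks per sample.** Within each sample, values are replaced by
   dense ranks (smallest value 1, ties share a rank, next distinct value
   increments by one). Dense ranks depend only on the within-sample
   ordering, so any strictly increasing platform transform — log, scanner
   calibration, RMA vs TPM — leaves them untouched. Missing entries are
   excluded and stay `NA`.
2. **Within-cohort mean imputation.** A missing gene value is replaced by
   the mean of that gene over the other samples of the same cohort.
   Imputation runs on the ranked scale, after ranking and before
   correction: ranks are the model's working units, and imputing earlier
   would let a cohort's missingness pattern perturb its own ranks. Mean
   imputation preserves per-gene cohort means exactly, which the tests
   assert as an identity.
3. **Reference-batch empirical-Bayes correction.** The ComBat
   location/scale model in its reference-batch variant: per gene, all
   samples are standardized by the *reference* cohort's mean and variance;
   per-batch location (γ) and scale (δ²) estimates of the other cohorts
   are shrunk by parametric empirical Bayes (normal prior on γ,
   inverse-gamma prior on δ², hyperparameters by method of moments, the
   usual iterative conditional solution run to a relative tolerance of
   1e-4); adjusted values are mapped back to the reference scale. The
   reference cohort is returned numerically unchanged — this is the
   property that lets a model locked on reference-scale data stay valid
   forever. The implementation is in-package because downstream code needs
   the full `batch_model` (estimates, hyperparameters, posteriors); the
   test suite cross-checks it against an independent reference
   implementation to ~1e-8.

For clinical cohorts whose biology matches only a subset of the reference
(for example breast tumors against a pan-cancer reference), the correction
accepts a `reference_samples` mask restricting which reference samples
define the standardization, without changing the anchor semantics.

The state flag on `expr_matrix` (`raw → ranked → corrected`) makes the
canonical order mechanical: ranking rejects non-raw input, imputation and
correction reject non-ranked input, scoring rejects a state different from
the model's training state.

## The phenocopy classifier

Features are the expression rows of a declared pathway gene set (shipped
and read as GMT), in gene-set order. The learner is a gradient-boosted
tree ensemble (binary logistic objective) with deliberately conservative
defaults: `eta = 0.1`, depth 3, up to 300 rounds with early stopping
(25 rounds) on a seeded stratified 15% validation split, row and column
subsampling 0.8, positives weighted to prevalence. The claims of this
package are about the pipeline, not a particular tuning, so all of these
are plain config values. Training is single-threaded and fully seeded:
identical data + seed give byte-identical serialized models, which the
determinism tests assert at the file-checksum level.

A 5-fold seeded stratified cross-validation reports the training-cohort
AUC against the *genotype* labels. Note an intentional subtlety: the
generator plants phenocopies *without* the genotype at rate π among
genotype-negative samples, so even a perfect phenotype detector cannot
exceed an AUC of roughly 1 − π/2 against genotype labels. Held-out
discrimination is therefore evaluated against the hidden phenotype truth
(the quantity the signature actually estimates), and the label-referenced
AUC is reported alongside.

Scores are binarized at a fixed 0.5 posterior probability by default — the
minimal-assumption cutoff, since no principled prevalence is available for
an arbitrary scored cohort. A training-prevalence quantile rule is
available (`set_threshold(model, "prevalence_quantile")`). Models are
locked: scoring never refits, missing feature genes are a hard error
unless the explicit `reference_mean` override is given, and
save → load → score is bit-identical to in-memory scoring.

## Association analyses

* **Per-drug linear models**: OLS of a sensitivity metric on intercept +
  phenocopy score + genotype. All supported metrics (IC50 z-score,
  −ActArea, −AUC) are oriented so *lower = more sensitive*; a negative
  phenocopy coefficient therefore means the phenocopy state predicts
  sensitivity. p-values use the t distribution with n − p degrees of
  freedom. No multiple-testing correction is applied to the per-drug
  results themselves; a Benjamini-Hochberg column is emitted alongside for
  the reader.
* **Fisher's exact test** on 2×2 phenocopy × response tables, two-sided by
  the sum-of-smaller-probability convention (relative tie tolerance 1e-7).
  The reported odds ratio is the sample OR ad/bc with a Haldane 0.5
  correction on zero cells. A zero margin returns p = 1 with a degenerate
  flag instead of an exception.
* **Cochran-Armitage trend test** for ordered 2×k tables (RCB classes 0-III,
  longitudinal timepoints), statistic
  T = Σᵢ sᵢ(x₁ᵢ − nᵢR₁/N) standardized by
  p(1−p)(Σnᵢsᵢ² − (Σnᵢsᵢ)²/N). This normalization was chosen so that the
  squared statistic at k = 2 reduces exactly to the Pearson chi-square
  without continuity correction, and the statistic is invariant under
  affine score changes; default scores are 0..k−1.
* **Adjusted pCR model**: ML logistic regression of pCR on phenocopy +
  grade + T/N stage (ordinal integer coding by default, indicator coding
  switchable), Wald z p-values. Separation is detected from the fit
  diagnostics (non-convergence, |coef| > 15, or extreme fitted
  probabilities with |coef| > 10) and raised as an error — never silently
  returned as an exploded coefficient.
* **Rate summaries** report per-stratum phenocopy proportions with exact
  Clopper-Pearson 95% intervals; empty strata yield n = 0 rows, not
  errors.

Pooled 2×2 counts across cohorts are used for the aggregate pCR test, with
per-ER-status tables emitted as well. Longitudinal rows are treated as
independent observations; repeated samples from the same patient are not
modelled, which is a known simplification.

## The synthetic generator

The generator plants the causal chain the analyses assume:

* genotype: biallelic TP53 loss with probability `genotype_loss_rate`
  (default 0.3, the order of dual-loss prevalence in pan-cancer tumor
  cohorts), realized as two coding mutations, mutation + CN loss, or MDM2
  amplification, always consistent with the labelling rules under the
  declared scheme — so called labels must equal generator truth exactly,
  and the tests require that;
* phenotype: every genotype-loss sample is phenotype-positive; a fraction
  π = `phenocopy_without_genotype_rate` (default 0.15) of the rest are
  phenocopies without the genotype;
* expression: i.i.d. Gaussian background per gene (mean ~ N(7, 2), SD ~
  U(0.5, 1.5)), every pathway gene of phenotype-positive samples shifted
  by δ = `pathway_effect_size` (default 0.5, i.e. about half a typical
  gene SD), then per-gene location/scale batch perturbations applied to
  the non-reference cohorts — batch effects come *after* the signal, so
  the harmonization layer has real work to do;
* responses: drug sensitivity = β·phenotype + noise (β = −0.5, SD 1);
  pCR ~ Bernoulli(logit⁻¹(α + b·phenotype)) with α = logit(0.21) and
  b = 0.62, the log-odds gap implied by pooled response rates of 33% vs
  21%; RCB is a discretized latent residual-burden variable whose mean
  drops by 0.8 for phenotype-positive samples (class 0 coincides with
  pCR); longitudinal cohorts resample the baseline with phenotype-positive
  samples retained at 0.6 (on-treatment) and 0.35 (post-treatment),
  emulating depletion of chemo-sensitive phenocopy tumors.

No published effect sizes exist on this scale, so δ, β, π and the
retention rates were chosen once for statistical power at the study sizes
the package is exercised at — small enough that the classifier is not
trivially perfect, large enough that the planted associations are
detectable — and are not tuned thereafter. Decoy structure (mono-allelic
mutations, silent-only variants) is planted among genotype-negative
samples so the labeller's exclusion rules are actually load-bearing.

What the generator does **not** emulate: RNA-seq count distributions
(values are Gaussian; ranking makes the workflow indifferent to this),
copy-number segments, tumor purity and subclonality, correlated gene-gene
structure, and patient-level dependence of longitudinal samples. Passing
tests therefore demonstrate that the machinery is correct under the
planted model, not that the signature generalizes to any particular real
cohort.

## Problem sizes and reproducibility

The reference study configuration is a 2000-sample reference cohort for
training plus held-out cohorts of 1000 (scoring and clinical analyses) and
3000 (pCR power checks) samples over 1000 genes and a 50-gene pathway;
unit tests exercise the same code paths at a few hundred samples. All
randomness flows from one integer seed, expanded per stage by a named
sub-seed derivation, and the simulate/train stages are byte-identical
under a fixed seed — asserted via file checksums.

## Known limitations

* The trend test uses the unconditional-variance normalization (required
  for the exact k = 2 chi-square identity); the difference from the
  N/(N−1) hypergeometric variance is negligible at the table sizes used
  but visible in principle at very small N.
* Mean imputation understates variance for genes with substantial
  missingness; the workflow targets the small, sporadic missingness
  typical of curated expression tables.
* The reference-batch correction assumes every cohort shares the pathway's
  rank structure up to location/scale distortions per gene; cohorts with
  genuinely different biology in the pathway genes would be partially
  "corrected" toward the reference.
* The phenocopy threshold of 0.5 is a convention, not an optimum; rate
  comparisons across cohorts scored with different thresholds are not
  meaningful.
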