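#' Configuration for the synthetic multi-cohort generator
#'
#' Defines the planted causal structure genotype -> phenotype -> response
#' that the whole workflow is validated against: biallelic TP53 loss
#' (genotype) always produces the expression phenotype; a fraction `pi` of
#' non-genotype samples carry the phenotype anyway (the phenocopies);
#' phenotype shifts the pathway genes, lowers drug-sensitivity values
#' (lower = more sensitive) and raises the pCR log-odds.
#'
#' @param n_samples_per_cohort positive integer, scalar or one per cohort.
#' @param n_cohorts number of cohorts (cohort 1 is the pan-cancer reference
#'   the batch correction anchors to).
#' @param n_genes_total,n_pathway_genes total and pathway gene counts;
#'   `n_pathway_genes <= n_genes_total`.
#' @param genotype_loss_rate probability of biallelic TP53 loss.
#' @param phenocopy_without_genotype_rate `pi`, fraction of non-genotype
#'   samples that still carry the expression phenotype.
#' @param pathway_effect_size `delta`, additive mean shift applied to every
#'   pathway gene of phenotype-positive samples on the raw expression scale
#'   (per-gene SDs are drawn from U(0.5, 1.5), so `delta` is of order one
#'   gene-SD), before batch effects.
#' @param batch_location_sd,batch_scale_sd dispersion of the per-gene
#'   per-batch location shifts and log scale factors applied to
#'   non-reference cohorts.
#' @param drug_effect `beta`, sensitivity shift for phenotype-positive lines
#'   (negative = phenotype increases sensitivity).
#' @param drug_noise_sd positive noise SD of the sensitivity metric.
#' @param pcr_logit_intercept,pcr_logit_phenocopy_beta logit model for the
#'   pCR flag: `logit P(pCR) = intercept + beta * phenotype`.
#' @param drugs drug names in the response table.
#' @param missing_rate fraction of expression cells masked to NA.
#' @param cn_scheme threshold-scheme name the emitted copy-number calls are
#'   consistent with.
#' @param timepoint_retention named probabilities that a phenotype-positive
#'   sample is retained in the on- and post-treatment longitudinal cohorts
#'   (phenotype-negative samples are always retained), emulating depletion
#'   of chemo-sensitive phenocopy tumors over treatment.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_samples_per_cohort = 500L,
                              n_cohorts = 3L,
                              n_genes_total = 1000L,
                              n_pathway_genes = 50L,
                              genotype_loss_rate = 0.3,
                              phenocopy_without_genotype_rate = 0.15,
                              pathway_effect_size = 0.5,
                              batch_location_sd = 0.3,
                              batch_scale_sd = 0.1,
                              drug_effect = -0.5,
                              drug_noise_sd = 1,
                              pcr_logit_intercept = stats::qlogis(0.21),
                              pcr_logit_phenocopy_beta = 0.62,
                              drugs = c("cisplatin", "docetaxel", "doxorubicin",
                                        "paclitaxel", "gemcitabine"),
                              missing_rate = 0,
                              cn_scheme = "gistic_le_minus1",
                              timepoint_retention = c(on = 0.6, post = 0.35),
                              seed = 1L) {
  cfg <- list(n_samples_per_cohort = as.integer(n_samples_per_cohort),
              n_cohorts = as.integer(n_cohorts),
              n_genes_total = as.integer(n_genes_total),
              n_pathway_genes = as.integer(n_pathway_genes),
              genotype_loss_rate = genotype_loss_rate,
              phenocopy_without_genotype_rate = phenocopy_without_genotype_rate,
              pathway_effect_size = pathway_effect_size,
              batch_location_sd = batch_location_sd,
              batch_scale_sd = batch_scale_sd,
              drug_effect = drug_effect,
              drug_noise_sd = drug_noise_sd,
              pcr_logit_intercept = pcr_logit_intercept,
              pcr_logit_phenocopy_beta = pcr_logit_phenocopy_beta,
              drugs = drugs,
              missing_rate = missing_rate,
              cn_scheme = cn_scheme,
              timepoint_retention = timepoint_retention,
              seed = as.integer(seed))
  for (f in c("genotype_loss_rate", "phenocopy_without_genotype_rate",
              "missing_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("configuration error: ", f, " must be a probability in [0,1]")
  }
  for (f in c("n_cohorts", "n_genes_total", "n_pathway_genes")) {
    v <- cfg[[f]]
    if (any(is.na(v)) || any(v < 1L))
      stop("configuration error: ", f, " must be a positive integer")
  }
  if (any(is.na(cfg$n_samples_per_cohort)) || any(cfg$n_samples_per_cohort < 0L))
    stop("configuration error: n_samples_per_cohort must be nonnegative")
  if (!length(cfg$n_samples_per_cohort) %in% c(1L, cfg$n_cohorts))
    stop("configuration error: n_samples_per_cohort must be scalar or one per cohort")
  if (cfg$n_pathway_genes > cfg$n_genes_total)
    stop("configuration error: n_pathway_genes must be <= n_genes_total")
  if (cfg$batch_location_sd < 0 || cfg$batch_scale_sd < 0)
    stop("configuration error: batch SDs must be nonnegative")
  if (cfg$drug_noise_sd <= 0)
    stop("configuration error: drug_noise_sd must be positive")
  if (any(cfg$timepoint_retention < 0) || any(cfg$timepoint_retention > 1) ||
      !all(c("on", "post") %in% names(cfg$timepoint_retention)))
    stop("configuration error: timepoint_retention needs probabilities named 'on' and 'post'")
  threshold_scheme(cfg$cn_scheme)  # validates the name
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate multi-cohort data with a planted phenocopy structure
#'
#' Background expression is i.i.d. Gaussian per gene (gene-specific mean
#' ~ N(7, 2), SD ~ U(0.5, 1.5)); phenotype-positive samples get every
#' pathway gene shifted by `pathway_effect_size` before batch effects;
#' non-reference cohorts then receive per-gene location/scale perturbations.
#' Mutation and copy-number calls are emitted consistently with the
#' genotype-calling rules under `cn_scheme`, including mono-allelic and
#' silent-only decoys and MDM2-amplified cases. Drug sensitivity is
#' `drug_effect * phenotype + noise`; pCR is drawn from the stated logit;
#' RCB class is a discretized latent residual-burden variable whose mean is
#' lower for phenotype-positive samples (class 0 coincides with pCR);
#' longitudinal timepoints are built by resampling with phenotype-positive
#' samples preferentially dropped on/post treatment.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_cohort` list: `expression` (raw `expr_matrix`),
#'   `mutations`, `copy_number`, `cn_value_kind`, `cn_scheme`, `clinical`
#'   (long over timepoints), `drug_response`, `truth`, `pathway` (a
#'   `gene_set`), `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_cohorts
  n_per <- rep(config$n_samples_per_cohort, length.out = nc)
  cohorts <- c("TCGA_SYN", if (nc > 1L) sprintf("COHORT_%02d", 2:nc))
  n <- sum(n_per)
  sample_ids <- unlist(lapply(seq_len(nc), function(i)
    sprintf("%s_S%04d", cohorts[i], seq_len(n_per[i]))), use.names = FALSE)
  batch <- rep(cohorts, times = n_per)

  g_path <- sprintf("PWY_%03d", seq_len(config$n_pathway_genes))
  g_bg <- if (config$n_genes_total > config$n_pathway_genes)
    sprintf("BGD_%04d", seq_len(config$n_genes_total - config$n_pathway_genes))
  else character(0)
  genes <- c(g_path, g_bg)

  # hidden states
  genotype <- stats::runif(n) < config$genotype_loss_rate
  phenotype <- genotype |
    (stats::runif(n) < config$phenocopy_without_genotype_rate)

  # expression: gene-specific background, pathway shift, then batch effects
  mu <- stats::rnorm(length(genes), 7, 2)
  sd_g <- stats::runif(length(genes), 0.5, 1.5)
  expr <- matrix(stats::rnorm(length(genes) * n, mu, sd_g),
                 nrow = length(genes), ncol = n,
                 dimnames = list(genes, sample_ids))
  if (any(phenotype))
    expr[g_path, phenotype] <- expr[g_path, phenotype] +
      config$pathway_effect_size
  expr_clean <- expr
  for (b in cohorts[-1L]) {
    cols <- which(batch == b)
    loc <- stats::rnorm(length(genes), 0, config$batch_location_sd)
    scl <- exp(stats::rnorm(length(genes), 0, config$batch_scale_sd))
    expr[, cols] <- mu + loc + scl * (expr[, cols] - mu)
  }
  if (config$missing_rate > 0 && n > 0) {
    mask <- stats::runif(length(expr)) < config$missing_rate
    expr[mask] <- NA_real_
  }

  # alterations consistent with the genotype-calling rules
  scheme <- threshold_scheme(config$cn_scheme)
  gistic <- scheme$value_kind == "gistic_discrete"
  mechanism <- rep("none", n)
  if (any(genotype))
    mechanism[genotype] <- sample(c("two_mut", "mut_cn", "two_mut_cn", "mdm2_amp"),
                                  sum(genotype), replace = TRUE,
                                  prob = c(0.4, 0.4, 0.1, 0.1))
  ng <- which(!genotype)
  if (length(ng)) {
    u <- stats::runif(length(ng))
    mechanism[ng[u < 0.2]] <- "single_mut"
    mechanism[ng[u >= 0.2 & u < 0.3]] <- "silent_only"
  }

  coding_pair <- c("Missense_Mutation", "Nonsense_Mutation")
  cn_loss_value <- function(k) {
    if (!gistic) return(stats::runif(k, -2.5, -1.2))
    if (scheme$name == "gistic_lt_minus1") rep(-2, k)
    else sample(c(-1, -2), k, replace = TRUE)
  }
  cn_neutral <- function(k) if (gistic) rep(0, k) else stats::rnorm(k, 0, 0.2)
  mut_rows <- list(); cn_tp53 <- cn_neutral(n); cn_mdm2 <- cn_neutral(n)
  add_mut <- function(s, gene, cls)
    data.frame(Tumor_Sample_Barcode = s, Hugo_Symbol = gene,
               Variant_Classification = cls)
  for (m in c("two_mut", "mut_cn", "two_mut_cn", "mdm2_amp", "single_mut",
              "silent_only")) {
    idx <- which(mechanism == m)
    if (!length(idx)) next
    s <- sample_ids[idx]
    if (m %in% c("two_mut", "two_mut_cn")) {
      mut_rows[[length(mut_rows) + 1L]] <- add_mut(rep(s, each = 2),
        "TP53", rep(coding_pair, length(s)))
    }
    if (m %in% c("mut_cn", "single_mut")) {
      mut_rows[[length(mut_rows) + 1L]] <- add_mut(s, "TP53",
        sample(coding_pair, length(s), replace = TRUE))
    }
    if (m == "silent_only")
      mut_rows[[length(mut_rows) + 1L]] <- add_mut(s, "TP53", "Silent")
    if (m %in% c("mut_cn", "two_mut_cn")) cn_tp53[idx] <- cn_loss_value(length(idx))
    if (m == "mdm2_amp") cn_mdm2[idx] <- if (gistic) rep(2, length(idx))
                                         else stats::runif(length(idx), 1.2, 2.5)
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows)
    else data.frame(Tumor_Sample_Barcode = character(0),
                    Hugo_Symbol = character(0),
                    Variant_Classification = character(0))
  copy_number <- data.frame(
    sample = rep(sample_ids, 2L),
    gene = rep(c("TP53", "MDM2"), each = n),
    value = c(cn_tp53, cn_mdm2))

  # clinical: covariates, pCR from the stated logit, RCB, ER, timepoints
  pcr_p <- stats::plogis(config$pcr_logit_intercept +
                         config$pcr_logit_phenocopy_beta * phenotype)
  pcr <- as.integer(stats::runif(n) < pcr_p)
  er_status <- sample(c("positive", "negative"), n, replace = TRUE,
                      prob = c(0.55, 0.45))
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.45, 0.35))
  t_stage <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
  n_stage <- sample(0:3, n, replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
  latent <- 2 - 0.8 * phenotype + stats::rnorm(n, 0, 0.8)
  rcb_class <- ifelse(pcr == 1L, 0L,
                      1L + findInterval(latent, c(1.2, 2.2)))

  base_clin <- data.frame(sample = sample_ids, cohort = batch,
                          er_status = er_status, pcr = pcr,
                          rcb_class = rcb_class, grade = grade,
                          t_stage = t_stage, n_stage = n_stage)
  keep_on <- !phenotype | stats::runif(n) < config$timepoint_retention[["on"]]
  keep_post <- !phenotype | stats::runif(n) < config$timepoint_retention[["post"]]
  clinical <- rbind(
    cbind(base_clin, timepoint = rep("pre", n)),
    cbind(base_clin[keep_on, , drop = FALSE], timepoint = rep("on", sum(keep_on))),
    cbind(base_clin[keep_post, , drop = FALSE], timepoint = rep("post", sum(keep_post))))
  rownames(clinical) <- NULL

  drug_response <- data.frame(
    sample = rep(sample_ids, times = length(config$drugs)),
    drug = rep(config$drugs, each = n),
    value = config$drug_effect * rep(as.numeric(phenotype), length(config$drugs)) +
      stats::rnorm(n * length(config$drugs), 0, config$drug_noise_sd),
    metric_kind = rep("z_ic50", n * length(config$drugs)))

  truth <- data.frame(sample = sample_ids, cohort = batch,
                      genotype_loss = genotype,
                      phenotype_positive = phenotype,
                      mechanism = mechanism)

  structure(list(
    expression = expression_matrix(expr, stats::setNames(batch, sample_ids)),
    expression_clean = expression_matrix(expr_clean,
                                         stats::setNames(batch, sample_ids)),
    mutations = mutations,
    copy_number = copy_number,
    cn_value_kind = scheme$value_kind,
    cn_scheme = config$cn_scheme,
    clinical = clinical,
    drug_response = drug_response,
    truth = truth,
    pathway = gene_set("TP53_CELL_CYCLE_SYNTHETIC", g_path,
                       "synthetic planted pathway"),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genes, %d cohorts\n",
              ncol(x$expression$values), nrow(x$expression$values),
              length(unique(x$expression$batch))))
  cat(sprintf("  genotype-loss %.1f%%, phenotype-positive %.1f%%\n",
              100 * mean(x$truth$genotype_loss),
              100 * mean(x$truth$phenotype_positive)))
  invisible(x)
}

#' Write a synthetic cohort as the workflow's fixture file set
#'
#' Emits the seven shared-format files: `expression.tsv`, `mutations.tsv`,
#' `copy_number.tsv`, `clinical.tsv`, `drug_response.tsv`, `pathway.gmt`,
#' and `truth.tsv` (hidden states; written for evaluation only, never read
#' by the analysis stages).
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if needed).
#' @return named character vector of file paths (the manifest), invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  p <- function(f) file.path(directory, f)
  write_expression_tsv(cohort$expression, p("expression.tsv"))
  write_tsv(cohort$mutations, p("mutations.tsv"))
  write_cn_tsv(cohort$copy_number, p("copy_number.tsv"))
  write_tsv(cohort$clinical, p("clinical.tsv"))
  write_tsv(cohort$drug_response, p("drug_response.tsv"))
  write_gmt(cohort$pathway, p("pathway.gmt"))
  write_tsv(cohort$truth, p("truth.tsv"))
  manifest <- c(expression = p("expression.tsv"), mutations = p("mutations.tsv"),
                copy_number = p("copy_number.tsv"), clinical = p("clinical.tsv"),
                drug_response = p("drug_response.tsv"), pathway = p("pathway.gmt"),
                truth = p("truth.tsv"))
  invisible(manifest)
}

#' Read a fixture directory back into memory
#'
#' @param directory directory written by [write_fixture()].
#' @param read_truth also read `truth.tsv` (default `TRUE`; analysis code
#'   should pass `FALSE`).
#' @param skip_expression skip the expression matrix (for stages that only
#'   need the clinical/alteration tables).
#' @return a list with the same data elements as a `synthetic_cohort`
#'   (no config).
#' @export
read_fixture <- function(directory, read_truth = TRUE,
                         skip_expression = FALSE) {
  p <- function(f) file.path(directory, f)
  clinical <- read_tsv_checked(p("clinical.tsv"),
    c("sample", "cohort", "er_status", "pcr", "rcb_class", "grade",
      "t_stage", "n_stage", "timepoint"))
  pre <- clinical[clinical$timepoint == "pre", , drop = FALSE]
  batch <- stats::setNames(as.character(pre$cohort), pre$sample)
  out <- list(
    expression = if (!skip_expression)
      read_expression_tsv(p("expression.tsv"), batch),
    mutations = read_tsv_checked(p("mutations.tsv"),
      c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")),
    copy_number = read_cn_tsv(p("copy_number.tsv")),
    clinical = clinical,
    drug_response = read_tsv_checked(p("drug_response.tsv"),
      c("sample", "drug", "value", "metric_kind")),
    pathway = read_gmt(p("pathway.gmt"))[[1L]])
  if (read_truth && file.exists(p("truth.tsv")))
    out$truth <- read_tsv_checked(p("truth.tsv"),
      c("sample", "cohort", "genotype_loss", "phenotype_positive"))
  out
}
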