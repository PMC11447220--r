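#' Pipeline configuration
#'
#' A single configuration list drives all workflow stages and serializes
#' losslessly to YAML (load -> dump -> load is a fixed point). Every source
#' of randomness flows from `seed`, expanded per stage by a named sub-seed
#' derivation ([derive_seed()]).
#'
#' @param fixture_dir directory holding the shared-format input files.
#' @param out_dir directory for stage outputs.
#' @param cn_scheme threshold-scheme name for genotype calling.
#' @param reference_batch batch the correction anchors to.
#' @param reference_samples optional sample subset of the reference batch
#'   used for standardization (e.g. a tissue-restricted reference).
#' @param model hyperparameter overrides for [train_model()].
#' @param threshold list(rule, value) for [set_threshold()].
#' @param simulation arguments for [simulation_config()] (used by
#'   [run_simulate()]).
#' @param seed master integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fixture_dir, out_dir = fixture_dir,
                            cn_scheme = "gistic_le_minus1",
                            reference_batch = "TCGA_SYN",
                            reference_samples = NULL,
                            model = list(),
                            threshold = list(rule = "fixed", value = 0.5),
                            simulation = list(),
                            seed = 1L) {
  structure(list(fixture_dir = fixture_dir, out_dir = out_dir,
                 cn_scheme = cn_scheme, reference_batch = reference_batch,
                 reference_samples = reference_samples, model = model,
                 threshold = threshold, simulation = simulation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Derive a named stage sub-seed from the master seed
#'
#' Deterministic, stage-named expansion of the master seed so that stages
#' draw from independent streams while the whole run stays reproducible
#' from one integer. Kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Load / save pipeline configuration as YAML
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

#' @rdname load_config
#' @param config a `pipeline_config`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(config, stage, inputs = character(0), outputs = character(0)) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("seed: %d (stage sub-seed %d)", config$seed,
            derive_seed(config$seed, stage)),
    sprintf("input %s md5 %s", inputs, tools::md5sum(inputs)),
    sprintf("output %s md5 %s", outputs, tools::md5sum(outputs)))
  writeLines(lines, file.path(config$out_dir, paste0(stage, ".log")))
  invisible(lines)
}

#' Simulate a fixture directory
#'
#' Runs the synthetic generator under the config's `simulation` settings
#' (seeded by the stage sub-seed unless the simulation block sets its own)
#' and writes the fixture file set to `fixture_dir`.
#'
#' @param config a `pipeline_config`.
#' @return the file manifest, invisibly.
#' @export
run_simulate <- function(config) {
  sim_args <- config$simulation
  if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(config$seed, "simulate")
  sim_cfg <- do.call(simulation_config, sim_args)
  cohort <- simulate_cohorts(sim_cfg)
  manifest <- write_fixture(cohort, config$fixture_dir)
  stage_log(config, "simulate", outputs = manifest)
  invisible(manifest)
}

harmonize_fixture <- function(fx, config) {
  ranked <- dense_rank_normalize(fx$expression)
  ranked <- impute_missing(ranked)
  combat_correct(ranked, config$reference_batch, config$reference_samples)
}

#' Train and lock the phenocopy model from a fixture directory
#'
#' label -> harmonize (rank, impute, reference-batch correct) -> restrict
#' to the pathway -> train -> set threshold. Training uses the
#' reference-batch samples only (the pan-cancer reference cohort); the
#' remaining cohorts are reserved as held-out validation material for
#' [run_score()]. Writes `model.json` and `training_report.tsv`
#' (cross-validated AUC and in-sample phenocopy rates by genotype class).
#'
#' @param config a `pipeline_config`.
#' @return list with `model`, `labels`, `report`, `paths`.
#' @export
run_train <- function(config) {
  fx <- read_fixture(config$fixture_dir, read_truth = FALSE)
  scheme <- threshold_scheme(config$cn_scheme)
  labels <- tryCatch(
    call_tp53_loss(fx$mutations, fx$copy_number, scheme,
                   samples = colnames(fx$expression$values)),
    error = function(e) stop("stage label: ", conditionMessage(e)))
  corrected <- tryCatch(harmonize_fixture(fx, config)$matrix,
    error = function(e) stop("stage harmonize: ", conditionMessage(e)))
  train_samples <- colnames(corrected$values)[corrected$batch == config$reference_batch]
  features <- tryCatch(
    select_features(subset_expr(corrected, samples = train_samples), fx$pathway),
    error = function(e) stop("stage select: ", conditionMessage(e)))
  model <- tryCatch(
    train_model(features, labels, hyperparameters = config$model,
                seed = derive_seed(config$seed, "train")),
    error = function(e) stop("stage train: ", conditionMessage(e)))
  model <- do.call(set_threshold,
                   c(list(model), config$threshold[c("rule", "value")]))

  calls <- score_samples(model, features)
  lab <- labels[match(calls$sample, labels$sample), ]
  rates <- summarize_phenocopy_rates(calls,
    stats::setNames(lab$allele_class, lab$sample))
  report <- data.frame(
    metric = c("cv_mean_auc", "cv_pooled_auc",
               paste0("insample_phenocopy_rate_", rates$stratum)),
    value = c(model$cv$mean_auc, model$cv$pooled_auc, rates$proportion))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(model = file.path(config$out_dir, "model.json"),
             report = file.path(config$out_dir, "training_report.tsv"))
  save_phenocopy_model(model, paths["model"])
  write_tsv(report, paths["report"])
  stage_log(config, "train",
            inputs = file.path(config$fixture_dir,
                               c("expression.tsv", "mutations.tsv",
                                 "copy_number.tsv", "pathway.gmt")),
            outputs = paths)
  list(model = model, labels = labels, report = report, paths = paths)
}

#' Score held-out cohorts with a locked model
#'
#' Harmonizes the fixture's cohorts against the declared reference (the
#' locked model's working scale) and applies the model without modification
#' to the non-reference samples. Writes `scores.tsv`.
#'
#' @param config a `pipeline_config`.
#' @param model a `phenocopy_model` or path to a model JSON.
#' @param samples optional sample subset to score (default: all
#'   non-reference samples).
#' @return data.frame of calls, invisibly written to `scores.tsv`.
#' @export
run_score <- function(config, model, samples = NULL) {
  if (is.character(model)) model <- load_phenocopy_model(model)
  fx <- read_fixture(config$fixture_dir, read_truth = FALSE)
  corrected <- tryCatch(harmonize_fixture(fx, config)$matrix,
    error = function(e) stop("stage harmonize: ", conditionMessage(e)))
  if (is.null(samples))
    samples <- colnames(corrected$values)[corrected$batch != config$reference_batch]
  calls <- score_samples(model, subset_expr(corrected, samples = samples))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$out_dir, "scores.tsv")
  write_tsv(calls, out)
  stage_log(config, "score",
            inputs = file.path(config$fixture_dir, "expression.tsv"),
            outputs = out)
  invisible(calls)
}

#' Run the validation analyses on scored samples
#'
#' Runs the clinical and in-vitro association suite on the scored samples:
#' pooled Fisher test of pCR vs phenocopy (plus per-ER-status tests),
#' Cochran-Armitage trend over RCB classes and over longitudinal
#' timepoints, phenocopy-rate summaries, per-drug sensitivity models (with
#' a BH column), and the covariate-adjusted pCR logistic model. One results
#' TSV per analysis under `out_dir`.
#'
#' @param config a `pipeline_config`.
#' @param calls scores data.frame (from [run_score()]) or path to
#'   `scores.tsv`.
#' @return named list of result data.frames, invisibly.
#' @export
run_validate <- function(config, calls) {
  if (is.character(calls)) calls <- read_tsv_checked(calls,
    c("sample", "score", "phenocopy"))
  calls$phenocopy <- as.logical(calls$phenocopy)
  fx <- read_fixture(config$fixture_dir, read_truth = FALSE,
                     skip_expression = TRUE)
  clin <- fx$clinical[fx$clinical$timepoint == "pre" &
                      fx$clinical$sample %in% calls$sample, , drop = FALSE]
  flag <- stats::setNames(calls$phenocopy, calls$sample)
  results <- list()

  if (nrow(clin) == 0L) {
    warning("no scored pre-treatment clinical samples; writing headers-only results")
    results$pcr_fisher <- association_result(character(0), character(0),
      character(0), numeric(0), numeric(0), numeric(0), numeric(0), integer(0))
  } else {
    tab <- function(d) {
      ph <- flag[d$sample]
      rbind(phenocopy = c(sum(ph & d$pcr == 0), sum(ph & d$pcr == 1)),
            not_phenocopy = c(sum(!ph & d$pcr == 0), sum(!ph & d$pcr == 1)))
    }
    pooled <- fisher_exact_2x2(tab(clin), "pcr_pooled")
    by_er <- lapply(split(clin, clin$er_status), function(d)
      fisher_exact_2x2(tab(d), paste0("pcr_er_", d$er_status[1L])))
    results$pcr_fisher <- do.call(rbind, c(list(pooled), unname(by_er)))

    rcb_tab <- t(vapply(c(TRUE, FALSE), function(ph)
      vapply(0:3, function(k)
        sum(flag[clin$sample] == ph & clin$rcb_class == k), 0), numeric(4)))
    results$rcb_trend <- cochran_armitage_trend(rcb_tab, model_id = "rcb_trend")

    long <- fx$clinical[fx$clinical$sample %in% calls$sample, , drop = FALSE]
    tps <- intersect(c("pre", "on", "post"), unique(long$timepoint))
    tp_tab <- t(vapply(c(TRUE, FALSE), function(ph)
      vapply(tps, function(t)
        sum(flag[long$sample[long$timepoint == t]] == ph), 0), numeric(length(tps))))
    results$timepoint_trend <- cochran_armitage_trend(tp_tab,
                                                      model_id = "timepoint_trend")
    results$timepoint_rates <- summarize_phenocopy_rates(calls,
      data.frame(sample = long$sample, stratum = long$timepoint))
    results$er_rates <- summarize_phenocopy_rates(calls,
      data.frame(sample = clin$sample, stratum = clin$er_status))
    results$pcr_adjusted <- tryCatch(
      adjusted_pcr_model(clin, calls), error = function(e) {
        warning("adjusted pCR model failed: ", conditionMessage(e))
        NULL
      })
  }

  drugs <- fx$drug_response[fx$drug_response$sample %in% calls$sample, ,
                            drop = FALSE]
  if (nrow(drugs)) {
    scheme <- threshold_scheme(config$cn_scheme)
    genotype <- call_tp53_loss(fx$mutations, fx$copy_number, scheme,
                               samples = calls$sample)
    results$drug_models <- drug_sensitivity_all(drugs, calls, genotype)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  for (nm in names(results)) {
    if (is.null(results[[nm]])) next
    f <- file.path(config$out_dir, paste0("results_", nm, ".tsv"))
    write_tsv(results[[nm]], f)
    outs <- c(outs, f)
  }
  stage_log(config, "validate",
            inputs = file.path(config$fixture_dir,
                               c("clinical.tsv", "drug_response.tsv")),
            outputs = outs)
  invisible(results)
}
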