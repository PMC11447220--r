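# one moderately sized harmonized cohort shared across signature tests
sig_env <- new.env()
sig_setup <- function() {
  if (!is.null(sig_env$data)) return(sig_env$data)
  co <- simulate_cohorts(quick_config(n_samples_per_cohort = c(400L, 250L),
                                      seed = 29L))
  corrected <- harmonize(co)
  labels <- call_tp53_loss(co$mutations, co$copy_number,
                           threshold_scheme(co$cn_scheme))
  features <- select_features(corrected, co$pathway)
  ref <- colnames(features$values)[features$batch == "TCGA_SYN"]
  held <- setdiff(colnames(features$values), ref)
  model <- train_model(subset_expr(features, samples = ref), labels,
                       seed = 101L, cv_folds = 3L)
  sig_env$data <- list(co = co, labels = labels, features = features,
                       ref = ref, held = held, model = model)
  sig_env$data
}

test_that("feature selection intersects in gene-set order and reports drops", {
  v <- matrix(rnorm(12), 3, dimnames = list(c("B", "C", "D"), paste0("s", 1:4)))
  x <- expression_matrix(v, rep("A", 4), state = "ranked")
  gs <- gene_set("toy", c("A", "B", "C"))
  out <- suppressMessages(select_features(x, gs))
  expect_identical(rownames(out$values), c("B", "C"))
  expect_identical(attr(out, "dropped_genes"), "A")
  # identity restriction
  gs_all <- gene_set("all", c("B", "C", "D"))
  expect_identical(select_features(x, gs_all)$values, v)
  expect_error(select_features(x, gene_set("off", c("X", "Y"))), "no gene")
  # the generator's planted signal genes are all retained
  d <- sig_setup()
  expect_identical(rownames(d$features$values), d$co$pathway$genes)
})

test_that("training is deterministic and separates planted classes", {
  d <- sig_setup()
  m2 <- train_model(subset_expr(d$features, samples = d$ref), d$labels,
                    seed = 101L, cv_folds = 0L)
  expect_identical(d$model$booster_raw, m2$booster_raw)
  expect_identical(d$model$training_scores, m2$training_scores)
  expect_gt(d$model$cv$mean_auc, 0.8)
  # held-out discrimination of the hidden phenotype state (sanity bound at
  # this reduced size; the full design point is checked below)
  calls <- score_samples(d$model, subset_expr(d$features, samples = d$held))
  truth <- d$co$truth[match(d$held, d$co$truth$sample), ]
  expect_gt(auc_score(truth$phenotype_positive, calls$score), 0.8)
})

test_that("a clearly separated cohort at full size is almost perfectly ranked", {
  co <- simulate_cohorts(simulation_config(
    n_samples_per_cohort = c(2000L, 1000L), n_cohorts = 2L,
    pathway_effect_size = 1.0, seed = 51L))
  corrected <- harmonize(co)
  labels <- call_tp53_loss(co$mutations, co$copy_number,
                           threshold_scheme(co$cn_scheme))
  features <- select_features(corrected, co$pathway)
  ref <- colnames(features$values)[features$batch == "TCGA_SYN"]
  held <- setdiff(colnames(features$values), ref)
  m <- train_model(subset_expr(features, samples = ref), labels,
                   seed = 61L, cv_folds = 0L)
  calls <- score_samples(m, subset_expr(features, samples = held))
  truth <- co$truth[match(held, co$truth$sample), ]
  expect_gte(auc_score(truth$phenotype_positive, calls$score), 0.95)
  # at the reference effect size, most true phenocopies without the
  # genotype are called at the default 0.5 threshold
  co2 <- simulate_cohorts(simulation_config(
    n_samples_per_cohort = c(2000L, 1000L), n_cohorts = 2L, seed = 52L))
  corrected2 <- harmonize(co2)
  labels2 <- call_tp53_loss(co2$mutations, co2$copy_number,
                            threshold_scheme(co2$cn_scheme))
  features2 <- select_features(corrected2, co2$pathway)
  ref2 <- colnames(features2$values)[features2$batch == "TCGA_SYN"]
  held2 <- setdiff(colnames(features2$values), ref2)
  m2 <- train_model(subset_expr(features2, samples = ref2), labels2,
                    seed = 62L, cv_folds = 0L)
  calls2 <- score_samples(m2, subset_expr(features2, samples = held2))
  truth2 <- co2$truth[match(held2, co2$truth$sample), ]
  pw <- truth2$phenotype_positive & !truth2$genotype_loss
  expect_gte(mean(calls2$phenocopy[pw]), 0.8)
})

test_that("permuted labels carry no signal", {
  d <- sig_setup()
  set.seed(202)
  shuffled <- d$labels
  shuffled$tp53_loss <- sample(shuffled$tp53_loss)
  m_null <- train_model(subset_expr(d$features, samples = d$ref), shuffled,
                        seed = 303L, cv_folds = 3L)
  # null AUC stays inside a 99% normal band around 0.5 (Hanley-McNeil SE)
  y <- shuffled$tp53_loss[match(d$ref, shuffled$sample)]
  n1 <- sum(y); n2 <- sum(!y)
  se <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  expect_lt(abs(m_null$cv$pooled_auc - 0.5), 2.6 * se)
})

test_that("single-class labels are rejected", {
  d <- sig_setup()
  neg <- d$labels
  neg$tp53_loss <- FALSE
  expect_error(train_model(subset_expr(d$features, samples = d$ref), neg),
               "single class")
})

test_that("scoring is locked: deterministic, never refits", {
  d <- sig_setup()
  train_mat <- subset_expr(d$features, samples = d$ref)
  calls1 <- score_samples(d$model, train_mat)
  expect_equal(stats::setNames(calls1$score, calls1$sample),
               d$model$training_scores)
  held_mat <- subset_expr(d$features, samples = d$held)
  expect_identical(score_samples(d$model, held_mat),
                   score_samples(d$model, held_mat))
  expect_true(all(calls1$score >= 0 & calls1$score <= 1))
  expect_identical(calls1$phenocopy, calls1$score >= d$model$threshold)
})

test_that("missing feature genes error unless the override is given", {
  d <- sig_setup()
  dropped <- subset_expr(d$features, genes = d$co$pathway$genes[-1],
                         samples = d$held)
  expect_error(score_samples(d$model, dropped), d$co$pathway$genes[1])
  filled <- score_samples(d$model, dropped, fill_missing = "reference_mean")
  expect_identical(nrow(filled), length(d$held))
  # state mismatch is rejected
  raw <- expression_matrix(d$features$values, d$features$batch, "raw")
  expect_error(score_samples(d$model, raw), "state")
})

test_that("all-reference-mean input yields one well-defined score", {
  d <- sig_setup()
  v <- matrix(rep(d$model$feature_means, 2), ncol = 2,
              dimnames = list(names(d$model$feature_means), c("m1", "m2")))
  x <- expression_matrix(v, c("A", "A"), state = "corrected")
  s1 <- score_samples(d$model, x)
  s2 <- score_samples(d$model, x)
  expect_identical(s1$score[1], s1$score[2])
  expect_identical(s1, s2)
})

test_that("threshold rules behave as specified", {
  d <- sig_setup()
  m <- set_threshold(d$model, "fixed", 0.5)
  fake <- m
  fake$threshold <- 0.5
  expect_identical(m$threshold, 0.5)
  expect_error(set_threshold(d$model, "fixed", 0), "inside")
  expect_error(set_threshold(d$model, "fixed", 1), "inside")
  # prevalence-quantile rule: called-positive fraction matches prevalence
  mq <- set_threshold(d$model, "prevalence_quantile")
  prev <- mq$metadata$n_positive / mq$metadata$n_train
  called <- mean(mq$training_scores >= mq$threshold)
  expect_lt(abs(called - prev), 2 / mq$metadata$n_train + 1e-9)
  # binarization at 0.5: (0.4, 0.6) -> (FALSE, TRUE)
  expect_identical(c(0.4, 0.6) >= m$threshold, c(FALSE, TRUE))
})

test_that("save -> load -> score is bit-identical to in-memory scoring", {
  d <- sig_setup()
  path <- withr::local_tempfile(fileext = ".json")
  save_phenocopy_model(d$model, path)
  back <- load_phenocopy_model(path)
  held_mat <- subset_expr(d$features, samples = d$held)
  expect_identical(score_samples(back, held_mat)$score,
                   score_samples(d$model, held_mat)$score)
  expect_identical(back$feature_genes, d$model$feature_genes)
  expect_identical(back$threshold, d$model$threshold)
})

test_that("held-out AUC never decreases with the planted effect size", {
  aucs <- sapply(c(0.15, 0.5, 1.0), function(delta) {
    reps <- sapply(c(401L, 402L), function(s) {
      co <- simulate_cohorts(quick_config(n_samples_per_cohort = c(300L, 200L),
                                          pathway_effect_size = delta,
                                          seed = s))
      corrected <- harmonize(co)
      labels <- call_tp53_loss(co$mutations, co$copy_number,
                               threshold_scheme(co$cn_scheme))
      features <- select_features(corrected, co$pathway)
      ref <- colnames(features$values)[features$batch == "TCGA_SYN"]
      held <- setdiff(colnames(features$values), ref)
      m <- train_model(subset_expr(features, samples = ref), labels,
                       seed = 7L, cv_folds = 0L)
      calls <- score_samples(m, subset_expr(features, samples = held))
      truth <- co$truth[match(held, co$truth$sample), ]
      auc_score(truth$phenotype_positive, calls$score)
    })
    mean(reps)
  })
  mc_se <- 0.03  # generous one-MC-SE allowance on a 2-replicate mean
  expect_gte(aucs[2], aucs[1] - mc_se)
  expect_gte(aucs[3], aucs[2] - mc_se)
})
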