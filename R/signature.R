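#' Restrict an expression matrix to a pathway gene set
#'
#' Returns the rows for the intersection of the gene set and the matrix
#' genes, in gene-set order, and reports dropped genes via the
#' `"dropped_genes"` attribute (and a message).
#'
#' @param x an `expr_matrix` with state `"corrected"` (or `"ranked"` for a
#'   single-cohort matrix).
#' @param geneset a [gene_set()].
#' @return an `expr_matrix` restricted to the pathway genes.
#' @export
select_features <- function(x, geneset) {
  stopifnot(inherits(x, "expr_matrix"), inherits(geneset, "gene_set"))
  if (!x$state %in% c("corrected", "ranked"))
    stop("select_features expects a ranked or corrected matrix, got '",
         x$state, "'")
  keep <- geneset$genes[geneset$genes %in% rownames(x$values)]
  dropped <- setdiff(geneset$genes, keep)
  if (!length(keep))
    stop("no gene of set '", geneset$name, "' is present in the matrix")
  if (length(dropped))
    message("select_features: dropped ", length(dropped),
            " gene(s) absent from the matrix: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...")
  out <- subset_expr(x, genes = keep)
  attr(out, "dropped_genes") <- dropped
  out
}

#' Area under the ROC curve
#'
#' Convenience wrapper around [pROC::roc()] with the orientation fixed so
#' that higher scores for positives give AUC > 0.5.
#'
#' @param labels logical (or 0/1) truth.
#' @param scores numeric scores.
#' @return AUC as a plain number.
#' @export
auc_score <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = as.logical(labels),
                                 predictor = as.numeric(scores),
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

default_hyperparameters <- function() {
  list(eta = 0.1, max_depth = 3L, nrounds = 300L, subsample = 0.8,
       colsample_bytree = 0.8, early_stopping_rounds = 25L,
       validation_fraction = 0.15)
}

xgb_params <- function(hp, scale_pos_weight, seed) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       eta = hp$eta, max_depth = hp$max_depth, subsample = hp$subsample,
       colsample_bytree = hp$colsample_bytree,
       scale_pos_weight = scale_pos_weight, nthread = 1L, seed = seed)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train and lock the phenocopy classifier
#'
#' Fits a gradient-boosted tree ensemble (binary logistic objective) on
#' pathway-restricted expression features against the biallelic TP53-loss
#' training label, with positives weighted to prevalence
#' (`scale_pos_weight`). A seeded stratified validation split drives early
#' stopping; a seeded stratified k-fold cross-validation reports the
#' training-cohort AUC. Training is fully deterministic given the seed
#' (single thread). Zero-variance features are retained (trees tolerate
#' them) but reported.
#'
#' @param features an `expr_matrix` of feature genes (see
#'   [select_features()]).
#' @param labels a logical vector named by sample, or a labels data.frame
#'   from [call_tp53_loss()] (its `tp53_loss` column is used).
#' @param hyperparameters list overriding [default_hyperparameters()].
#' @param seed integer seed.
#' @param cv_folds folds for the reported cross-validated AUC; `0` skips CV.
#' @param threshold initial probability cutoff for the binary call.
#' @return a `phenocopy_model`: `feature_genes`, `booster_raw` (JSON bytes),
#'   `hyperparameters`, `threshold`, `metadata` (seed, normalization state,
#'   class counts, zero-variance features), `training_scores`,
#'   `feature_means`, `cv` (per-fold and mean AUC, or `NULL`).
#' @export
train_model <- function(features, labels, hyperparameters = list(),
                        seed = 1L, cv_folds = 5L, threshold = 0.5) {
  stopifnot(inherits(features, "expr_matrix"))
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$tp53_loss, labels$sample)
  samples <- colnames(features$values)
  miss <- setdiff(samples, names(labels))
  if (length(miss))
    stop("unlabeled training sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
  y <- as.integer(labels[samples])
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; need both")

  hp <- utils::modifyList(default_hyperparameters(), hyperparameters)
  xmat <- t(features$values)
  if (anyNA(xmat)) stop("missing values in the feature matrix; impute first")
  zero_var <- rownames(features$values)[apply(features$values, 1L, stats::sd) == 0]
  if (length(zero_var))
    message("train_model: ", length(zero_var), " zero-variance feature(s) retained")
  spw <- sum(y == 0L) / sum(y == 1L)

  fit_once <- function(rows, sub_seed) {
    yr <- y[rows]
    val <- stratified_folds(yr, max(2L, round(1 / hp$validation_fraction)),
                            sub_seed) == 1L
    dtrain <- xgboost::xgb.DMatrix(xmat[rows, , drop = FALSE][!val, , drop = FALSE],
                                   label = yr[!val])
    dval <- xgboost::xgb.DMatrix(xmat[rows, , drop = FALSE][val, , drop = FALSE],
                                 label = yr[val])
    xgboost::xgb.train(params = xgb_params(hp, spw, sub_seed),
                       data = dtrain, nrounds = hp$nrounds,
                       evals = list(val = dval),
                       early_stopping_rounds = hp$early_stopping_rounds,
                       verbose = 0)
  }

  cv <- NULL
  if (cv_folds >= 2L) {
    fold <- stratified_folds(y, cv_folds, seed + 1000L)
    oof <- rep(NA_real_, length(y))
    fold_auc <- numeric(cv_folds)
    for (k in seq_len(cv_folds)) {
      bst <- fit_once(which(fold != k), seed + k)
      pred <- predict(bst, xgboost::xgb.DMatrix(xmat[fold == k, , drop = FALSE]))
      oof[fold == k] <- pred
      fold_auc[k] <- auc_score(y[fold == k] == 1L, pred)
    }
    cv <- list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
               pooled_auc = auc_score(y == 1L, oof))
  }

  bst <- fit_once(seq_along(y), seed)
  training_scores <- stats::setNames(
    predict(bst, xgboost::xgb.DMatrix(xmat)), samples)

  structure(list(
    feature_genes = rownames(features$values),
    booster_raw = xgboost::xgb.save.raw(bst, raw_format = "json"),
    hyperparameters = hp,
    threshold = threshold,
    metadata = list(seed = as.integer(seed),
                    normalization_state = features$state,
                    label_definition = "biallelic_tp53_loss_or_mdm2",
                    n_train = length(y), n_positive = sum(y),
                    scale_pos_weight = spw, zero_variance = zero_var),
    training_scores = training_scores,
    feature_means = rowMeans(features$values),
    cv = cv), class = "phenocopy_model")
}

#' @export
print.phenocopy_model <- function(x, ...) {
  cat(sprintf("phenocopy_model: %d features, threshold %.3f, trained on n=%d (%.1f%% positive)\n",
              length(x$feature_genes), x$threshold, x$metadata$n_train,
              100 * x$metadata$n_positive / x$metadata$n_train))
  if (!is.null(x$cv))
    cat(sprintf("  cross-validated AUC: %.3f (pooled %.3f)\n",
                x$cv$mean_auc, x$cv$pooled_auc))
  invisible(x)
}

#' Score samples with a locked phenocopy model
#'
#' Applies the locked classifier without any refitting. The input matrix
#' must be in the normalization state the model was trained on and contain
#' every feature gene (or `fill_missing = "reference_mean"` to substitute
#' the training mean rank for absent genes -- off by default because silent
#' fills corrupt locked-model inputs).
#'
#' @param model a `phenocopy_model`.
#' @param x an `expr_matrix`.
#' @param fill_missing `"error"` (default) or `"reference_mean"`.
#' @return data.frame `sample`, `score` (in \[0,1\]), `phenocopy`
#'   (`score >= threshold`).
#' @export
score_samples <- function(model, x, fill_missing = c("error", "reference_mean")) {
  stopifnot(inherits(model, "phenocopy_model"), inherits(x, "expr_matrix"))
  fill_missing <- match.arg(fill_missing)
  if (x$state != model$metadata$normalization_state)
    stop("matrix state '", x$state, "' does not match the model's '",
         model$metadata$normalization_state, "'")
  absent <- setdiff(model$feature_genes, rownames(x$values))
  if (length(absent) && fill_missing == "error")
    stop("feature gene(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  m <- matrix(NA_real_, length(model$feature_genes), ncol(x$values),
              dimnames = list(model$feature_genes, colnames(x$values)))
  present <- intersect(model$feature_genes, rownames(x$values))
  m[present, ] <- x$values[present, , drop = FALSE]
  if (length(absent)) m[absent, ] <- model$feature_means[absent]
  if (anyNA(m)) stop("missing values among feature genes; impute first")
  bst <- xgboost::xgb.load.raw(model$booster_raw)
  score <- predict(bst, xgboost::xgb.DMatrix(t(m)))
  data.frame(sample = colnames(x$values), score = as.numeric(score),
             phenocopy = as.numeric(score) >= model$threshold,
             row.names = NULL)
}

#' Set the binarization threshold of a locked model
#'
#' Either a fixed posterior-probability cutoff or a training-prevalence
#' quantile: the cutoff is placed so that the fraction of training samples
#' called positive matches the training-label prevalence (up to ties).
#'
#' @param model a `phenocopy_model`.
#' @param rule `"fixed"` or `"prevalence_quantile"`.
#' @param value cutoff for the fixed rule, in (0, 1).
#' @return the model with `threshold` updated.
#' @export
set_threshold <- function(model, rule = c("fixed", "prevalence_quantile"),
                          value = 0.5) {
  stopifnot(inherits(model, "phenocopy_model"))
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
        value <= 0 || value >= 1)
      stop("threshold must be strictly inside (0, 1)")
    model$threshold <- value
  } else {
    prev <- model$metadata$n_positive / model$metadata$n_train
    thr <- stats::quantile(model$training_scores, probs = 1 - prev,
                           names = FALSE, type = 1)
    if (thr <= 0 || thr >= 1)
      stop("prevalence-quantile threshold fell outside (0, 1)")
    model$threshold <- thr
  }
  model
}

#' Save a locked model to a JSON file
#'
#' Single JSON file embedding the ordered feature list, hyperparameters,
#' threshold, training metadata, training scores and the booster dump.
#' Serialization is deterministic, so identical training runs give
#' byte-identical files.
#'
#' @param model a `phenocopy_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_phenocopy_model <- function(model, path) {
  stopifnot(inherits(model, "phenocopy_model"))
  obj <- list(
    format = "tp53phenocopy_model", version = 1L,
    feature_genes = model$feature_genes,
    hyperparameters = model$hyperparameters,
    threshold = model$threshold,
    metadata = model$metadata,
    training_scores = as.list(model$training_scores),
    feature_means = as.list(model$feature_means),
    cv = model$cv,
    booster_json = rawToChar(model$booster_raw))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a locked model from a JSON file
#'
#' @param path file written by [save_phenocopy_model()].
#' @return a `phenocopy_model` whose scores are bit-identical to the
#'   in-memory model's.
#' @export
load_phenocopy_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tp53phenocopy_model"))
    stop(path, " is not a phenocopy model file")
  structure(list(
    feature_genes = obj$feature_genes,
    booster_raw = charToRaw(obj$booster_json),
    hyperparameters = obj$hyperparameters,
    threshold = obj$threshold,
    metadata = obj$metadata,
    training_scores = unlist(obj$training_scores),
    feature_means = unlist(obj$feature_means),
    cv = obj$cv), class = "phenocopy_model")
}
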