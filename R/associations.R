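association_result <- function(model_id, kind, covariate, coef, se, stat, p, n,
                               extra = list()) {
  res <- data.frame(model = model_id, kind = kind, covariate = covariate,
                    coef = coef, se = se, stat = stat, p = p, n = n,
                    row.names = NULL)
  for (nm in names(extra)) attr(res, nm) <- extra[[nm]]
  res
}

#' Per-drug multivariable sensitivity model
#'
#' Ordinary least squares of a drug-sensitivity metric (oriented so lower =
#' more sensitive: IC50 z-score, -ActArea, -AUC) on intercept + phenocopy +
#' genotype. A negative phenocopy coefficient therefore means the phenocopy
#' state is associated with increased sensitivity. Two-sided p-values from
#' the t distribution with n - p degrees of freedom.
#'
#' @param response data.frame `sample`, `drug`, `value`, `metric_kind`.
#' @param calls phenocopy calls data.frame (`sample`, `score`, `phenocopy`)
#'   or a named numeric/logical vector; the continuous score is used when
#'   `use_score = TRUE` (default, matching the modelling choice of scoring
#'   on the probability scale), otherwise the binary call.
#' @param genotype labels data.frame from [call_tp53_loss()] or a named
#'   logical vector.
#' @param drug drug name to model.
#' @param use_score use the continuous phenocopy score (default) or the
#'   binary call.
#' @return an association-result data.frame (rows: phenocopy, genotype)
#'   with columns `model`, `kind`, `covariate`, `coef`, `se`, `stat`, `p`,
#'   `n`.
#' @export
drug_sensitivity_lm <- function(response, calls, genotype, drug,
                                use_score = TRUE) {
  r <- response[response$drug == drug, , drop = FALSE]
  if (!nrow(r)) stop("no response records for drug '", drug, "'")
  if (is.data.frame(calls)) {
    pheno <- stats::setNames(if (use_score) calls$score
                             else as.numeric(calls$phenocopy), calls$sample)
  } else pheno <- stats::setNames(as.numeric(calls), names(calls))
  if (is.data.frame(genotype))
    genotype <- stats::setNames(as.numeric(genotype$tp53_loss), genotype$sample)
  else genotype <- stats::setNames(as.numeric(genotype), names(genotype))
  keep <- r$sample %in% names(pheno) & r$sample %in% names(genotype)
  r <- r[keep, , drop = FALSE]
  d <- data.frame(y = r$value, phenocopy = pheno[r$sample],
                  genotype = genotype[r$sample])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 3L + 3L)
    stop("too few samples for drug '", drug, "': n = ", n,
         " (need at least 3 more than parameters)")
  X <- stats::model.matrix(~ phenocopy + genotype, d)
  if (qr(X)$rank < ncol(X))
    stop("singular design for drug '", drug,
         "': phenocopy and genotype are collinear")
  fit <- stats::lm(y ~ phenocopy + genotype, data = d)
  cf <- summary(fit)$coefficients
  rows <- c("phenocopy", "genotype")
  association_result(paste0("drug:", drug), "linear", rows,
                     cf[rows, 1L], cf[rows, 2L], cf[rows, 3L], cf[rows, 4L],
                     n)
}

#' Fit sensitivity models for every drug, with a BH column
#'
#' Convenience sweep over all drugs in the response table; raw per-drug
#' p-values are reported unchanged and a Benjamini-Hochberg adjusted column
#' (`p_bh`, computed within covariate across drugs) is added for the
#' reader's benefit.
#'
#' @inheritParams drug_sensitivity_lm
#' @return row-bound association results with a `p_bh` column.
#' @export
drug_sensitivity_all <- function(response, calls, genotype, use_score = TRUE) {
  drugs <- unique(response$drug)
  res <- do.call(rbind, lapply(drugs, function(d)
    drug_sensitivity_lm(response, calls, genotype, d, use_score)))
  res$p_bh <- NA_real_
  for (cv in unique(res$covariate))
    res$p_bh[res$covariate == cv] <- stats::p.adjust(res$p[res$covariate == cv],
                                                     "BH")
  res
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' p-value by the standard convention: the sum of hypergeometric
#' probabilities of all margin-fixed tables whose probability does not
#' exceed the observed table's (relative tolerance 1e-7 for ties), as
#' computed by [stats::fisher.test()]. The odds ratio reported is the
#' sample OR ad/bc, with a Haldane 0.5-cell correction when any cell is
#' zero. A zero margin yields p = 1 with a `degenerate` flag rather than an
#' error.
#'
#' @param table 2x2 matrix of nonnegative integer counts; rows phenocopy /
#'   not phenocopy, columns the ordered outcome (e.g. no-pCR / pCR).
#' @param model_id identifier for the result row.
#' @return association-result data.frame with attributes `odds_ratio` and
#'   `degenerate`.
#' @export
fisher_exact_2x2 <- function(table, model_id = "fisher") {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  if (degenerate) {
    p <- 1
    or <- NA_real_
  } else {
    p <- stats::fisher.test(table)$p.value
    tt <- table
    if (any(tt == 0)) tt <- tt + 0.5
    or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  }
  res <- association_result(model_id, "fisher", "phenocopy", NA_real_,
                            NA_real_, NA_real_, p, sum(table),
                            extra = list(odds_ratio = or,
                                         degenerate = degenerate))
  res$odds_ratio <- or  # column survives rbind across cohort results
  res
}

#' Cochran-Armitage test for trend across ordered categories
#'
#' Tests for a monotone trend in the row-1 proportion across the ordered
#' columns of a 2 x k table. The trend statistic is
#' `T = sum_i s_i (x_1i - n_i R_1 / N)` with column scores `s_i`,
#' standardized by the null variance
#' `p(1-p) (sum_i n_i s_i^2 - (sum_i n_i s_i)^2 / N)` with `p = R_1/N`,
#' and referred to the standard normal (two-sided). With this normalization
#' the squared statistic at k = 2 equals the Pearson chi-square without
#' continuity correction, and the statistic is invariant under affine
#' transformations of the scores. A table with an all-zero row (or zero
#' variance) returns p = 1 with a `degenerate` flag.
#'
#' @param table 2 x k matrix of nonnegative counts, columns in their
#'   natural order.
#' @param scores numeric column scores; default `0:(k-1)`.
#' @param model_id identifier for the result row.
#' @return association-result data.frame (`stat` is the signed Z) with a
#'   `degenerate` attribute.
#' @export
cochran_armitage_trend <- function(table, scores = NULL, model_id = "trend") {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("need a 2 x k table with k >= 2")
  if (any(table < 0)) stop("counts must be nonnegative")
  k <- ncol(table)
  if (is.null(scores)) scores <- seq_len(k) - 1
  if (length(scores) != k) stop("need one score per column")
  x1 <- table[1L, ]
  n_i <- colSums(table)
  N <- sum(n_i)
  R1 <- sum(x1)
  p <- R1 / N
  v <- p * (1 - p) * (sum(n_i * scores^2) - sum(n_i * scores)^2 / N)
  degenerate <- R1 == 0 || R1 == N || v <= 0
  if (degenerate) {
    z <- 0; pval <- 1
  } else {
    t_stat <- sum(scores * (x1 - n_i * p))
    z <- t_stat / sqrt(v)
    pval <- 2 * stats::pnorm(-abs(z))
  }
  association_result(model_id, "trend", "trend", NA_real_, NA_real_, z, pval,
                     N, extra = list(degenerate = degenerate))
}

#' Covariate-adjusted logistic model for pCR
#'
#' Maximum-likelihood logistic regression of the pCR flag on the phenocopy
#' state plus pathologic grade and T/N stage (ordinal integer coding by
#' default, indicator coding switchable), with Wald z p-values. Complete or
#' quasi-complete separation raises an error with a diagnostic instead of
#' silently returning exploded coefficients.
#'
#' @param clinical data.frame with columns `sample`, `pcr` and the
#'   covariates.
#' @param calls phenocopy calls data.frame or named logical vector.
#' @param covariates covariate column names (default grade, t_stage,
#'   n_stage).
#' @param coding `"ordinal"` (integers as-is) or `"indicator"` (factors).
#' @param model_id identifier for the result rows.
#' @return association-result data.frame, one row per model term
#'   (phenocopy first).
#' @export
adjusted_pcr_model <- function(clinical, calls,
                               covariates = c("grade", "t_stage", "n_stage"),
                               coding = c("ordinal", "indicator"),
                               model_id = "pcr_adjusted") {
  coding <- match.arg(coding)
  if (is.data.frame(calls))
    calls <- stats::setNames(calls$phenocopy, calls$sample)
  miss <- setdiff(c("sample", "pcr", covariates), names(clinical))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- clinical[clinical$sample %in% names(calls), , drop = FALSE]
  d$phenocopy <- as.numeric(calls[d$sample])
  if (!all(d$pcr %in% c(0, 1))) stop("pcr must be binary 0/1")
  if (coding == "indicator")
    for (cv in covariates) d[[cv]] <- factor(d[[cv]])
  fml <- stats::as.formula(paste("pcr ~ phenocopy +",
                                 paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  max_coef <- max(abs(stats::coef(fit)), na.rm = TRUE)
  extreme_fit <- any(stats::fitted(fit) < 1e-10 | stats::fitted(fit) > 1 - 1e-10)
  if (!fit$converged || max_coef > 15 || (extreme_fit && max_coef > 10) ||
      (warned && max_coef > 10))
    stop("complete or quasi-complete separation detected (max |coef| = ",
         signif(max_coef, 3), "); the phenocopy/pCR likelihood is degenerate")
  terms <- setdiff(rownames(cf), "(Intercept)")
  terms <- c("phenocopy", setdiff(terms, "phenocopy"))
  association_result(model_id, "logistic", terms,
                     cf[terms, 1L], cf[terms, 2L], cf[terms, 3L], cf[terms, 4L],
                     nrow(d))
}

#' Phenocopy-call rates by stratum with exact binomial intervals
#'
#' @param calls phenocopy calls data.frame or named logical vector.
#' @param strata named character/factor vector of stratum labels (named by
#'   sample), or a vector aligned with `calls` rows; every scored sample
#'   must be stratified. Repeated sample ids (e.g. longitudinal rows) are
#'   allowed when `strata` carries its own `sample` mapping via
#'   `data.frame(sample, stratum)`.
#' @return data.frame `stratum`, `n`, `n_phenocopy`, `proportion`, `lower`,
#'   `upper` (Clopper-Pearson 95%); empty strata get `n = 0` and `NA`
#'   proportions, never an error.
#' @export
summarize_phenocopy_rates <- function(calls, strata) {
  if (is.data.frame(calls))
    calls <- stats::setNames(calls$phenocopy, calls$sample)
  if (is.data.frame(strata)) {
    if (!all(c("sample", "stratum") %in% names(strata)))
      stop("strata data.frame needs columns sample, stratum")
    miss <- setdiff(strata$sample, names(calls))
    if (length(miss)) stop("unscored sample(s) in strata: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    flags <- as.logical(calls[strata$sample])
    labs <- strata$stratum
  } else if (!is.null(names(strata))) {
    miss <- setdiff(names(calls), names(strata))
    if (length(miss)) stop("unstratified sample(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    flags <- as.logical(calls)
    labs <- strata[names(calls)]
  } else {
    if (length(strata) != length(calls))
      stop("strata must be named or aligned with calls")
    flags <- as.logical(calls)
    labs <- strata
  }
  labs <- if (is.factor(labs)) labs else factor(labs, levels = unique(labs))
  out <- do.call(rbind, lapply(levels(labs), function(l) {
    f <- flags[labs == l]
    n <- length(f); x <- sum(f)
    if (n == 0L)
      return(data.frame(stratum = l, n = 0L, n_phenocopy = 0L,
                        proportion = NA_real_, lower = NA_real_,
                        upper = NA_real_))
    ci <- stats::binom.test(x, n)$conf.int
    data.frame(stratum = l, n = n, n_phenocopy = x, proportion = x / n,
               lower = ci[1L], upper = ci[2L])
  }))
  rownames(out) <- NULL
  out
}
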