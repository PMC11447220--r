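#' Gene-by-sample expression matrix with batch labels
#'
#' Light container used throughout the workflow: a numeric gene x sample
#' matrix plus a per-sample batch (cohort) label and a processing-state flag.
#' The state flag enforces the canonical pipeline order raw -> ranked ->
#' corrected: ranking only accepts raw input, batch correction only accepts
#' ranked input.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must be named and names must be unique. `NA` encodes missing.
#' @param batch character vector of batch labels, one per sample, either
#'   named by sample or in column order.
#' @param state one of `"raw"`, `"ranked"`, `"corrected"`.
#' @return an object of class `expr_matrix` (list with elements `values`,
#'   `batch`, `state`).
#' @export
expression_matrix <- function(values, batch, state = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must have gene rownames and sample colnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  state <- match.arg(state, c("raw", "ranked", "corrected"))
  batch <- as.character(batch)
  if (!is.null(names(batch))) {
    missing <- setdiff(colnames(values), names(batch))
    if (length(missing))
      stop("no batch label for sample(s): ", paste(missing, collapse = ", "))
    batch <- batch[colnames(values)]
  } else if (length(batch) == 1L) {
    batch <- rep(batch, ncol(values))
  } else if (length(batch) != ncol(values)) {
    stop("`batch` must have one label per sample")
  }
  names(batch) <- colnames(values)
  structure(list(values = values, batch = batch, state = state),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  cat("batches:", paste(sprintf("%s (n=%d)", names(table(x$batch)),
                                as.integer(table(x$batch))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an `expr_matrix`.
#' @param genes,samples character vectors; `NULL` keeps all.
#' @return an `expr_matrix` in the requested order, same state.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  g <- if (is.null(genes)) rownames(x$values) else genes
  s <- if (is.null(samples)) colnames(x$values) else samples
  bad <- setdiff(g, rownames(x$values))
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(s, colnames(x$values))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  expression_matrix(x$values[g, s, drop = FALSE], x$batch[s], x$state)
}

#' Dense-rank normalize each sample
#'
#' Replaces the values of every sample (column) by their dense ranks: the
#' smallest non-missing value maps to 1, tied values share a rank, and each
#' next distinct value increments the rank by exactly 1. Dense ranks depend
#' only on the ordering of values within a sample, which makes them invariant
#' to any strictly increasing platform-specific transform -- the property the
#' cross-platform harmonization relies on. Missing entries are excluded from
#' ranking and stay `NA`.
#'
#' @param x an `expr_matrix` with `state == "raw"`.
#' @return an `expr_matrix` with `state == "ranked"`.
#' @export
dense_rank_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$state != "raw")
    stop("dense_rank_normalize expects state 'raw', got '", x$state, "'")
  n_obs <- colSums(!is.na(x$values))
  if (any(n_obs == 0L))
    stop("sample(s) with zero non-missing values: ",
         paste(colnames(x$values)[n_obs == 0L], collapse = ", "))
  ranked <- apply(x$values, 2L, function(v) {
    r <- rep(NA_real_, length(v))
    obs <- !is.na(v)
    r[obs] <- match(v[obs], sort(unique(v[obs])))
    r
  })
  dimnames(ranked) <- dimnames(x$values)
  expression_matrix(ranked, x$batch, state = "ranked")
}

#' Impute missing entries by the within-cohort gene mean
#'
#' Each missing (gene, sample) cell is replaced by the mean of that gene over
#' all other samples of the same cohort (batch). Performed on the ranked
#' scale, before batch correction.
#'
#' @param x an `expr_matrix` with `state == "ranked"`.
#' @return an `expr_matrix`, same state, with no missing values.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$state != "ranked")
    stop("impute_missing expects state 'ranked' (impute after ranking, before correction), got '",
         x$state, "'")
  v <- x$values
  if (!anyNA(v)) return(x)
  for (b in unique(x$batch)) {
    cols <- which(x$batch == b)
    sub <- v[, cols, drop = FALSE]
    if (!anyNA(sub)) next
    gmeans <- rowMeans(sub, na.rm = TRUE)
    all_missing <- which(!is.finite(gmeans) & rowSums(!is.na(sub)) == 0L)
    if (length(all_missing))
      stop("gene(s) entirely missing within cohort '", b, "': ",
           paste(rownames(v)[all_missing], collapse = ", "))
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- gmeans[idx[, 1L]]
    v[, cols] <- sub
  }
  expression_matrix(v, x$batch, state = "ranked")
}
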