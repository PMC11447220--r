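# Shared file contracts: tab-delimited UTF-8 tables with a header row,
# missing values as literal NA. Expression and copy-number tables are
# gene x sample with the gene id in the first column.

read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "NA")
  if (!is.null(required)) {
    miss <- setdiff(required, names(d))
    if (length(miss))
      stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  d
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-by-sample expression TSV
#'
#' First column is the gene id, remaining columns are samples.
#'
#' @param path expression TSV.
#' @param batch named character vector or two-column data.frame
#'   (sample, batch) assigning each sample to a cohort.
#' @param state processing state of the stored values (default `"raw"`).
#' @return an `expr_matrix`.
#' @export
read_expression_tsv <- function(path, batch, state = "raw") {
  d <- read_tsv_checked(path)
  genes <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (is.data.frame(batch)) {
    b <- as.character(batch[[2L]]); names(b) <- as.character(batch[[1L]])
    batch <- b
  }
  expression_matrix(m, batch, state)
}

#' Write an expression matrix to TSV
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  d <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  write_tsv(d, path)
}

#' Read a gene-by-sample copy-number TSV into long form
#' @param path CN TSV (gene first column, samples across).
#' @return data.frame with columns `sample`, `gene`, `value`.
#' @export
read_cn_tsv <- function(path) {
  d <- read_tsv_checked(path)
  genes <- as.character(d[[1L]])
  samples <- names(d)[-1L]
  if (!length(samples) || !length(genes))
    return(data.frame(sample = character(0), gene = character(0),
                      value = numeric(0)))
  long <- data.frame(
    sample = rep(samples, each = length(genes)),
    gene = rep(genes, times = length(samples)),
    value = as.numeric(as.matrix(d[, -1L, drop = FALSE])))
  long[!is.na(long$value), , drop = FALSE]
}

#' Write long-form copy-number records to a gene-by-sample TSV
#' @param cn data.frame with columns `sample`, `gene`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cn_tsv <- function(cn, path) {
  samples <- sort(unique(cn$sample))
  genes <- unique(cn$gene)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(cn)) m[cbind(match(cn$gene, genes), match(cn$sample, samples))] <- cn$value
  write_tsv(data.frame(gene = genes, m, check.names = FALSE), path)
}
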