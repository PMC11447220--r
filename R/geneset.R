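#' Gene set
#'
#' @param name set name.
#' @param genes ordered character vector of gene symbols; non-empty, no
#'   duplicates.
#' @param description optional free-text description.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes))
    stop("duplicate genes in set '", name, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: name, description, then symbols.
#'
#' @param path GMT file path.
#' @return named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[1L], f[-(1:2)], f[2L])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_set` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
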