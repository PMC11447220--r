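#' MAF variant-classification vocabulary
#'
#' Maps MAF-standard `Variant_Classification` strings to a coding flag and a
#' mutation-type category. Coding classifications are the protein-altering
#' ones; `Silent` and the various flank/intron/UTR/RNA classes are
#' non-coding and never count toward biallelic-loss calls. The mapping is a
#' plain data.frame so other dialects can be declared and passed in.
#'
#' @return data.frame with columns `classification`, `coding`, `category`.
#' @export
default_variant_vocabulary <- function() {
  rbind(
    data.frame(classification = "Missense_Mutation", coding = TRUE, category = "missense"),
    data.frame(classification = "Nonsense_Mutation", coding = TRUE, category = "nonsense"),
    data.frame(classification = c("Frame_Shift_Del", "Frame_Shift_Ins"),
               coding = TRUE, category = "frameshift"),
    data.frame(classification = c("In_Frame_Del", "In_Frame_Ins"),
               coding = TRUE, category = "inframe_indel"),
    data.frame(classification = c("Splice_Site", "Splice_Region"),
               coding = TRUE, category = "splice"),
    data.frame(classification = c("Nonstop_Mutation", "Translation_Start_Site"),
               coding = TRUE, category = "other_coding"),
    data.frame(classification = c("Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
                                  "Intron", "IGR", "RNA"),
               coding = FALSE, category = "non_coding")
  )
}

#' Classify variant-classification strings
#'
#' @param classification character vector of `Variant_Classification` values.
#' @param vocabulary mapping table as returned by
#'   [default_variant_vocabulary()].
#' @return data.frame with columns `classification`, `coding` (logical),
#'   `category`.
#' @export
classify_variant <- function(classification,
                             vocabulary = default_variant_vocabulary()) {
  idx <- match(classification, vocabulary$classification)
  if (anyNA(idx))
    stop("unknown variant classification(s): ",
         paste(unique(classification[is.na(idx)]), collapse = ", "))
  data.frame(classification = classification,
             coding = vocabulary$coding[idx],
             category = vocabulary$category[idx])
}

#' Copy-number loss threshold schemes
#'
#' Dataset-specific rules for calling gene-level copy-number loss:
#' `gistic_le_minus1` (discrete GISTIC value <= -1, the TCGA convention),
#' `gistic_lt_minus1` (discrete GISTIC value < -1, i.e. deep deletion only,
#' the GDSC convention), and `log2_lt_minus1` (log2 copy-number ratio < -1,
#' the CCLE convention).
#'
#' @param name scheme name.
#' @return list with `name`, `value_kind`, and the predicate `is_loss`.
#' @export
threshold_scheme <- function(name = c("gistic_le_minus1", "gistic_lt_minus1",
                                      "log2_lt_minus1")) {
  name <- match.arg(name)
  switch(name,
    gistic_le_minus1 = list(name = name, value_kind = "gistic_discrete",
                            is_loss = function(v) !is.na(v) & v <= -1),
    gistic_lt_minus1 = list(name = name, value_kind = "gistic_discrete",
                            is_loss = function(v) !is.na(v) & v < -1),
    log2_lt_minus1   = list(name = name, value_kind = "log2_ratio",
                            is_loss = function(v) !is.na(v) & v < -1))
}

#' Call biallelic TP53 loss from mutation and copy-number tables
#'
#' Implements the high-confidence loss-of-function genotype: a sample is
#' `dual_loss` when it carries two coding TP53 mutations, or one coding
#' TP53 mutation together with TP53 copy-number loss under the declared
#' threshold scheme. MDM2 alteration (amplification, optionally any coding
#' MDM2 mutation) phenocopies p53 loss by proteasomal degradation of
#' wild-type p53 and, by default, suffices on its own for the training label
#' `tp53_loss`. Non-coding variants never count. Samples present in either
#' table are labelled; a sample absent from one table is treated as
#' unaltered in that table.
#'
#' @param mutations data.frame with columns `Tumor_Sample_Barcode`,
#'   `Hugo_Symbol`, `Variant_Classification` (optionally `Protein_Change`).
#'   Identical duplicate records are collapsed before counting.
#' @param copy_number long data.frame with columns `sample`, `gene`, `value`.
#'   Duplicate (sample, gene) records with conflicting values are an error.
#' @param scheme a [threshold_scheme()].
#' @param value_kind declared kind of the copy-number values; must match the
#'   scheme's.
#' @param vocabulary variant vocabulary, see [classify_variant()].
#' @param mdm2_rule `"amplification_or_mutation"` (default) flags MDM2
#'   amplification (GISTIC >= 2 / log2 > 1) or any coding MDM2 mutation;
#'   `"amplification_only"` requires amplification; `"ignore"` never flags.
#' @param mdm2_sufficient if `TRUE` (default) `mdm2_altered` alone sets
#'   `tp53_loss = TRUE`.
#' @param samples optional character vector extending the labelled universe
#'   (e.g. expression-only samples, labelled unaltered).
#' @return data.frame with one row per sample: `sample`,
#'   `tp53_coding_mutation_count`, `tp53_cn_loss`, `mdm2_altered`,
#'   `allele_class` (`dual_loss`/`single_alteration`/`none`), `tp53_loss`.
#' @export
call_tp53_loss <- function(mutations, copy_number, scheme,
                           value_kind = scheme$value_kind,
                           vocabulary = default_variant_vocabulary(),
                           mdm2_rule = c("amplification_or_mutation",
                                         "amplification_only", "ignore"),
                           mdm2_sufficient = TRUE,
                           samples = NULL) {
  mdm2_rule <- match.arg(mdm2_rule)
  if (!identical(value_kind, scheme$value_kind))
    stop("value_kind '", value_kind, "' does not match scheme '",
         scheme$name, "' (expects '", scheme$value_kind, "')")
  req <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  if (!all(req %in% names(mutations)))
    stop("mutation table must have columns: ", paste(req, collapse = ", "))
  if (!all(c("sample", "gene", "value") %in% names(copy_number)))
    stop("copy-number table must have columns sample, gene, value")

  # deduplicate identical mutation records (same sample/gene/class/protein)
  key_cols <- intersect(c(req, "Protein_Change"), names(mutations))
  mutations <- mutations[!duplicated(mutations[, key_cols, drop = FALSE]), ,
                         drop = FALSE]
  # conflicting CN duplicates are an error; identical ones collapse
  copy_number <- copy_number[!duplicated(copy_number[, c("sample", "gene", "value")]), ,
                             drop = FALSE]
  dup <- duplicated(copy_number[, c("sample", "gene")])
  if (any(dup)) {
    bad <- unique(paste(copy_number$sample[dup], copy_number$gene[dup], sep = "/"))
    stop("conflicting duplicate copy-number records for: ",
         paste(bad, collapse = ", "))
  }

  universe <- sort(unique(c(mutations$Tumor_Sample_Barcode,
                            copy_number$sample, samples)))
  cls <- if (nrow(mutations)) classify_variant(mutations$Variant_Classification,
                                               vocabulary)
         else data.frame(coding = logical(0), category = character(0))

  tp53_mut <- mutations$Hugo_Symbol == "TP53" & cls$coding
  mut_count <- table(factor(mutations$Tumor_Sample_Barcode[tp53_mut],
                            levels = universe))
  mut_count <- as.integer(mut_count)

  cn_tp53 <- copy_number[copy_number$gene == "TP53", , drop = FALSE]
  cn_loss <- universe %in% cn_tp53$sample[scheme$is_loss(cn_tp53$value)]

  mdm2_amp_rule <- if (value_kind == "gistic_discrete") {
    function(v) !is.na(v) & v >= 2
  } else {
    function(v) !is.na(v) & v > 1
  }
  cn_mdm2 <- copy_number[copy_number$gene == "MDM2", , drop = FALSE]
  mdm2_amp <- universe %in% cn_mdm2$sample[mdm2_amp_rule(cn_mdm2$value)]
  mdm2_mut <- universe %in%
    mutations$Tumor_Sample_Barcode[mutations$Hugo_Symbol == "MDM2" & cls$coding]
  mdm2_altered <- switch(mdm2_rule,
    amplification_or_mutation = mdm2_amp | mdm2_mut,
    amplification_only = mdm2_amp,
    ignore = rep(FALSE, length(universe)))

  dual <- mut_count >= 2L | (mut_count >= 1L & cn_loss)
  single <- !dual & (mut_count >= 1L | cn_loss)
  allele_class <- ifelse(dual, "dual_loss",
                         ifelse(single, "single_alteration", "none"))
  tp53_loss <- dual | (mdm2_sufficient & mdm2_altered)

  data.frame(sample = universe,
             tp53_coding_mutation_count = mut_count,
             tp53_cn_loss = cn_loss,
             mdm2_altered = mdm2_altered,
             allele_class = allele_class,
             tp53_loss = tp53_loss,
             row.names = NULL)
}
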