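#' Fragments per kilobase of exon per million mapped fragments
#'
#' FPKM (equivalently RPKM for fragment-based counting) normalizes a
#' fragment count by transcript length and sequencing depth:
#' `count * 1e9 / (gene_length_bp * total_mapped_fragments)`.
#'
#' @param fragment_count Nonnegative integer vector of fragments assigned to
#'   the gene.
#' @param gene_length_bp Positive integer vector of exon-model lengths in
#'   base pairs.
#' @param total_mapped_fragments Positive integer scalar (or vector) of
#'   mapped fragments in the library.
#' @return Numeric vector of FPKM values.
#' @export
#' @examples
#' compute_fpkm(10, 1000, 1e6)   # 10 fragments per kb per million = 10
#' compute_fpkm(250, 2500, 2e7)  # 5
compute_fpkm <- function(fragment_count, gene_length_bp,
                         total_mapped_fragments) {
  if (!is.numeric(fragment_count) || any(fragment_count < 0, na.rm = TRUE)) {
    stop_invalid("'fragment_count' must be nonnegative")
  }
  if (!is.numeric(gene_length_bp) || any(gene_length_bp <= 0, na.rm = TRUE)) {
    stop_invalid("'gene_length_bp' must be positive")
  }
  if (!is.numeric(total_mapped_fragments) ||
      any(total_mapped_fragments <= 0, na.rm = TRUE)) {
    stop_invalid("'total_mapped_fragments' must be positive")
  }
  # double arithmetic: integer length x total overflows 32-bit
  as.numeric(fragment_count) * 1e9 /
    (as.numeric(gene_length_bp) * as.numeric(total_mapped_fragments))
}

#' Per-library expression table
#'
#' One genomotype's per-gene abundances: gene identifier, optional exon-model
#' length and fragment count, and FPKM abundance. Gene identifiers are opaque
#' strings; tables from different reference systems (e.g. de novo unigenes
#' vs genome-mapped gene ids) are never merged by this package.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param fpkm Nonnegative numeric vector of abundances (FPKM/RPKM units).
#' @param length Optional positive integer vector of gene lengths (bp);
#'   `NA` allowed per gene.
#' @param count Optional nonnegative numeric vector of fragment counts;
#'   `NA` allowed per gene.
#' @param library_label Character scalar naming the library (e.g. "liv-PAA").
#' @param genomotype Genomotype label or [genomotype()] object.
#' @return A `data.frame` of class `expression_table` with columns
#'   `gene_id`, `length`, `count`, `fpkm` and attributes `library_label`
#'   and `genomotype`.
#' @export
#' @examples
#' expression_table(c("g1", "g2"), fpkm = c(3.2, 0),
#'                  library_label = "liv-PA", genomotype = "PA")
expression_table <- function(gene_id, fpkm, length = NULL, count = NULL,
                             library_label = "library",
                             genomotype = "PA") {
  gene_id <- as.character(gene_id)
  n <- base::length(gene_id)  # the 'length' argument shadows base::length
  if (anyDuplicated(gene_id)) stop_invalid("duplicated gene_id values")
  if (base::length(fpkm) != n) {
    stop_invalid("'fpkm' length must match 'gene_id'")
  }
  if (is.null(length)) length <- rep(NA_integer_, n)
  if (is.null(count)) count <- rep(NA_real_, n)
  tbl <- data.frame(gene_id = gene_id,
                    length = as.integer(length),
                    count = as.numeric(count),
                    fpkm = as.numeric(fpkm),
                    stringsAsFactors = FALSE)
  gt <- as_genomotype(genomotype)
  structure(tbl,
            library_label = as.character(library_label),
            genomotype = gt$label,
            class = c("expression_table", "data.frame"))
}

#' Validate an expression table
#'
#' Diagnostic check of the expression-table invariants. Returns a character
#' vector of violations (empty when the table is valid); each violation
#' names the gene and the broken rule. When `total_mapped_fragments` is
#' supplied, the stored FPKM of every gene with both count and length is
#' checked against [compute_fpkm()] within relative tolerance `tol`.
#'
#' @param table An `expression_table`.
#' @param total_mapped_fragments Optional positive scalar: the library's
#'   total mapped fragments, enabling the FPKM-consistency check.
#' @param tol Relative tolerance for the FPKM-consistency check.
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_table <- function(table, total_mapped_fragments = NULL, tol = 1e-9) {
  violations <- character(0)
  if (!inherits(table, "expression_table")) {
    return("not an expression_table object")
  }
  need <- c("gene_id", "length", "count", "fpkm")
  if (!all(need %in% names(table))) {
    return(paste("missing column(s):",
                 paste(setdiff(need, names(table)), collapse = ", ")))
  }
  bad <- which(is.na(table$fpkm) | table$fpkm < 0)
  violations <- c(violations, sprintf(
    "gene %s: abundance must be a nonnegative real", table$gene_id[bad]))
  bad <- which(!is.na(table$length) & table$length <= 0)
  violations <- c(violations, sprintf(
    "gene %s: gene length must be positive", table$gene_id[bad]))
  bad <- which(!is.na(table$count) & table$count < 0)
  violations <- c(violations, sprintf(
    "gene %s: fragment count must be nonnegative", table$gene_id[bad]))
  if (!is.null(total_mapped_fragments)) {
    check_positive(total_mapped_fragments, "total_mapped_fragments")
    full <- which(!is.na(table$count) & !is.na(table$length) &
                    table$length > 0)
    if (length(full)) {
      expected <- compute_fpkm(table$count[full], table$length[full],
                               total_mapped_fragments)
      rel <- abs(table$fpkm[full] - expected) / pmax(abs(expected), 1e-300)
      off <- rel > tol & !(expected == 0 & table$fpkm[full] == 0)
      violations <- c(violations, sprintf(
        "gene %s: stored FPKM inconsistent with count/length/total",
        table$gene_id[full][off]))
    }
  }
  violations
}

#' Read an expression table from TSV
#'
#' Expects the four-column layout `gene_id  length  count  fpkm` with a
#' header line; missing counts/lengths are empty fields. UTF-8, LF line
#' endings, decimal point.
#'
#' @param path Path to the TSV file.
#' @inheritParams expression_table
#' @return An `expression_table`.
#' @export
read_expression_tsv <- function(path, library_label = basename(path),
                                genomotype = "PA") {
  if (!file.exists(path)) stop_invalid("expression TSV not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "numeric",
                                   "numeric"),
                    na.strings = c("", "NA"), stringsAsFactors = FALSE)
  need <- c("gene_id", "length", "count", "fpkm")
  if (!identical(names(raw), need)) {
    stop_invalid("expression TSV must have columns: ",
                 paste(need, collapse = ", "))
  }
  expression_table(raw$gene_id, fpkm = raw$fpkm, length = raw$length,
                   count = raw$count, library_label = library_label,
                   genomotype = genomotype)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_tsv()]; abundances are written with full
#' precision (15 significant digits) so a round trip preserves them to
#' better than 1e-12 relative error.
#'
#' @param table An `expression_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  out <- data.frame(gene_id = table$gene_id,
                    length = table$length,
                    count = ifelse(is.na(table$count), NA,
                                   format(table$count, digits = 15,
                                          scientific = FALSE, trim = TRUE)),
                    fpkm = format(table$fpkm, digits = 15, trim = TRUE),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
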