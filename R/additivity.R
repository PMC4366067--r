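#' Mid-parent (additive) expected expression for a hybrid
#'
#' Under the additivity expectation each haplome copy in a hybrid
#' contributes half of the corresponding parental diploid's expression.
#' For a genomotype with `copies_P` P copies and `copies_A` A copies the
#' expected abundance is `(copies_P * PP + copies_A * AA) / 2`, which
#' reduces to `PP/2 + AA/2` for PA and `PP/2 + AA/2 + AA/2` for PAA.
#'
#' @param pp_value,aa_value Nonnegative numeric vectors: the gene's
#'   abundance in the PP and AA parental diploid libraries.
#' @param genomotype Hybrid genomotype (label or [genomotype()] object);
#'   must use only the P and A haplomes.
#' @return Numeric vector of expected abundances.
#' @export
#' @examples
#' expected_additive(10, 10, "PAA")  # 15
#' expected_additive(10, 10, "PA")   # 10
expected_additive <- function(pp_value, aa_value, genomotype = "PAA") {
  if (any(pp_value < 0) || any(aa_value < 0)) {
    stop_invalid("parental abundances must be nonnegative")
  }
  gt <- as_genomotype(genomotype)
  if (!all(names(gt$haplome_copies) %in% c("P", "A"))) {
    stop_invalid("additivity expectation is defined only for P/A ",
                 "genomotypes, got haplomes: ",
                 paste(names(gt$haplome_copies), collapse = ", "))
  }
  copies <- function(h) {
    if (h %in% names(gt$haplome_copies)) gt$haplome_copies[[h]] else 0L
  }
  (copies("P") * pp_value + copies("A") * aa_value) / 2
}

#' Classify observed hybrid expression against the additivity expectation
#'
#' A gene is additively expressed when
#' `-1 < log2(observed / expected) < 1` (strict); below/above that window
#' it is below- or above-additive. When either value is zero the log ratio
#' is undefined and the gene receives the `undefined` category (excluded
#' from percentage summaries).
#'
#' @param observed,expected Nonnegative numeric vectors (FPKM).
#' @return Factor with levels `below_additive`, `additive`,
#'   `above_additive`, `undefined`.
#' @export
#' @examples
#' classify_additivity(c(7, 1, 8), c(7, 4, 4))
classify_additivity <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) {
    stop_invalid("'observed' and 'expected' must be nonnegative")
  }
  lr <- ifelse(observed > 0 & expected > 0, log2(observed / expected), NA)
  cat_chr <- ifelse(is.na(lr), "undefined",
             ifelse(abs(lr) < 1, "additive",
             ifelse(lr <= -1, "below_additive", "above_additive")))
  factor(cat_chr, levels = c("below_additive", "additive",
                             "above_additive", "undefined"))
}

#' Per-gene additivity records for a hybrid table
#'
#' Joins a hybrid expression table with its two parental diploid tables and
#' evaluates the additivity expectation gene by gene.
#'
#' @param pp,aa Parental `expression_table`s (PP and AA).
#' @param hybrid Hybrid `expression_table` (PA or PAA).
#' @param genomotype Hybrid genomotype; defaults to the hybrid table's
#'   `genomotype` attribute.
#' @return A `data.frame` with columns `gene_id`, `observed`, `expected`,
#'   `log2_obs_over_exp`, `category`.
#' @export
additivity_profile <- function(pp, aa, hybrid, genomotype = NULL) {
  if (is.null(genomotype)) genomotype <- attr(hybrid, "genomotype")
  shared <- Reduce(intersect, list(pp$gene_id, aa$gene_id, hybrid$gene_id))
  if (length(shared) == 0) {
    stop_invalid("no gene id shared by the three tables")
  }
  ppv <- pp$fpkm[match(shared, pp$gene_id)]
  aav <- aa$fpkm[match(shared, aa$gene_id)]
  obs <- hybrid$fpkm[match(shared, hybrid$gene_id)]
  exp_val <- expected_additive(ppv, aav, genomotype)
  category <- classify_additivity(obs, exp_val)
  data.frame(gene_id = shared,
             observed = obs,
             expected = exp_val,
             log2_obs_over_exp = ifelse(obs > 0 & exp_val > 0,
                                        log2(obs / exp_val), NA_real_),
             category = category,
             stringsAsFactors = FALSE)
}

#' Tally additivity categories
#'
#' Counts genes per additivity category and reports integer percentages of
#' the defined (non-`undefined`) genes. The chi-square balance test on the
#' two non-additive categories asks whether under- or over-expression
#' relative to the expectation dominates.
#'
#' @param records `data.frame` from [additivity_profile()], or any data
#'   frame with a `category` column.
#' @return List with `counts` (all four categories), `n_defined`,
#'   `percentages` (of defined genes, integers), and `chi_square_non_additive`
#'   (from [chi_square_goodness()] on below vs above counts, `NULL` when
#'   both are zero).
#' @export
additivity_tally <- function(records) {
  stopifnot(is.data.frame(records), "category" %in% names(records),
            nrow(records) > 0)
  cat_f <- factor(records$category,
                  levels = c("below_additive", "additive",
                             "above_additive", "undefined"))
  counts <- setNames(as.integer(table(cat_f)), levels(cat_f))
  defined <- counts[c("below_additive", "additive", "above_additive")]
  n_defined <- sum(defined)
  if (n_defined == 0) stop_invalid("no gene with a defined category")
  chi <- if (counts[["below_additive"]] + counts[["above_additive"]] > 0) {
    chi_square_goodness(counts[["below_additive"]],
                        counts[["above_additive"]])
  } else NULL
  list(counts = counts,
       n_defined = n_defined,
       percentages = round_half_away(100 * defined / n_defined),
       chi_square_non_additive = chi)
}
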