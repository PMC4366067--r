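#' Read / write long-format qPCR plate data
#'
#' The long CSV layout has one row per well:
#' `sample_id,genomotype,target,template,replicate,cq` with
#' `template` in `{cdna, gdna}` and decimal-point Cq values. cDNA-specific
#' wells measure expression; gDNA-specific wells measure genome copy number
#' and serve as the normalization reference.
#'
#' @param path CSV file path.
#' @return A `data.frame` with the six columns above.
#' @export
read_qpcr_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("qPCR CSV not found: ", path)
  qpcr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genomotype", "target", "template", "replicate",
            "cq")
  if (!all(need %in% names(qpcr))) {
    stop_invalid("qPCR CSV must have columns: ", paste(need, collapse = ", "))
  }
  validate_qpcr(qpcr)
  qpcr[need]
}

#' @rdname read_qpcr_csv
#' @param qpcr A qPCR `data.frame`.
#' @export
write_qpcr_csv <- function(qpcr, path) {
  validate_qpcr(qpcr)
  write.csv(qpcr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: structural checks on a long qPCR data frame
validate_qpcr <- function(qpcr) {
  stopifnot(is.data.frame(qpcr))
  if (!all(qpcr$template %in% c("cdna", "gdna"))) {
    stop_invalid("'template' must be 'cdna' or 'gdna'")
  }
  if (any(!is.finite(qpcr$cq)) || any(qpcr$cq <= 0)) {
    stop_invalid("Cq values must be finite and positive")
  }
  invisible(qpcr)
}

#' Genome-normalized relative expression by the Livak method
#'
#' Computes the relative expression per genome of one target gene between
#' two genomotypes from co-extracted cDNA/gDNA qPCR data, assuming
#' amplification efficiency 2:
#' \enumerate{
#'   \item technical replicates are averaged (arithmetic mean of Cq);
#'   \item per biological sample, `dCq = mean target cDNA Cq - arithmetic
#'     mean of the reference gDNA Cqs` — the Cq-scale equivalent of
#'     normalizing the linear quantity to the geometric mean of the
#'     genomic references, which turns expression into transcripts per
#'     genome copy;
#'   \item `ddCq = mean dCq(numerator genomotype) - mean dCq(denominator)`;
#'   \item `ratio_per_genome = 2^-ddCq`.
#' }
#' The spread `sd_ratio` is the standard deviation, across the numerator
#' genomotype's biological replicates, of `2^-(dCq - mean dCq(denominator))`.
#'
#' @param qpcr Long qPCR `data.frame` (see [read_qpcr_csv()]).
#' @param target Target gene measured with cDNA-specific primers.
#' @param reference_targets Genes measured with gDNA-specific primers in
#'   every sample (the study panel: rpl8, eef1a, actb2).
#' @param numerator_genomotype,denominator_genomotype Genomotype labels,
#'   e.g. `"PAA"` vs `"PA"`.
#' @return An object of class `genome_normalized_expression`: list with
#'   `target`, `per_sample_delta_cq`, `per_genomotype_mean_delta_cq`,
#'   `ratio_per_genome`, `sd_ratio`.
#' @export
livak_per_genome <- function(qpcr, target, reference_targets,
                             numerator_genomotype = "PAA",
                             denominator_genomotype = "PA") {
  validate_qpcr(qpcr)
  genos <- c(numerator_genomotype, denominator_genomotype)
  missing_geno <- setdiff(genos, unique(qpcr$genomotype))
  if (length(missing_geno)) {
    stop_invalid("genomotype(s) absent from qPCR data: ",
                 paste(missing_geno, collapse = ", "))
  }
  qpcr <- qpcr[qpcr$genomotype %in% genos, , drop = FALSE]
  samples <- unique(qpcr$sample_id)
  delta_cq <- setNames(numeric(length(samples)), samples)
  geno_of <- setNames(character(length(samples)), samples)
  for (s in samples) {
    sub <- qpcr[qpcr$sample_id == s, , drop = FALSE]
    geno_of[s] <- sub$genomotype[1]
    tgt <- sub$cq[sub$target == target & sub$template == "cdna"]
    if (length(tgt) == 0) {
      stop_invalid(sprintf("sample %s has no cDNA wells for target %s",
                           s, target))
    }
    ref_means <- vapply(reference_targets, function(r) {
      cqs <- sub$cq[sub$target == r & sub$template == "gdna"]
      if (length(cqs) == 0) {
        stop_invalid(sprintf("sample %s lacks gDNA reference target %s",
                             s, r))
      }
      mean(cqs)
    }, numeric(1))
    delta_cq[s] <- mean(tgt) - mean(ref_means)
  }
  mean_num <- mean(delta_cq[geno_of == numerator_genomotype])
  mean_den <- mean(delta_cq[geno_of == denominator_genomotype])
  dd_cq <- mean_num - mean_den
  per_sample_ratio_num <-
    2^-(delta_cq[geno_of == numerator_genomotype] - mean_den)
  structure(
    list(target = target,
         per_sample_delta_cq = delta_cq,
         per_genomotype_mean_delta_cq =
           setNames(c(mean_num, mean_den), genos),
         ratio_per_genome = 2^-dd_cq,
         sd_ratio = if (length(per_sample_ratio_num) > 1)
           sd(per_sample_ratio_num) else NA_real_),
    class = "genome_normalized_expression"
  )
}

#' Per-cell expression ratio from a per-genome ratio
#'
#' A cell of the numerator genomotype carries `numerator_ploidy` genome
#' copies against `denominator_ploidy` in the denominator, so expression
#' per cell scales the per-genome ratio by the ploidy quotient (1.5 for
#' PAA vs PA).
#'
#' @param per_genome_ratio Positive numeric vector.
#' @param numerator_ploidy,denominator_ploidy Positive integers.
#' @return Numeric vector.
#' @export
#' @examples
#' per_cell_ratio(0.8, 3, 2)  # 1.2
per_cell_ratio <- function(per_genome_ratio, numerator_ploidy = 3,
                           denominator_ploidy = 2) {
  check_positive(per_genome_ratio, "per_genome_ratio")
  stopifnot(numerator_ploidy >= 1, denominator_ploidy >= 1)
  per_genome_ratio * numerator_ploidy / denominator_ploidy
}

#' Relative transcriptome size from per-cell and per-transcriptome ratios
#'
#' Transcriptome-normalized abundances (FPKM ratios) measure expression per
#' transcriptome; genome-normalized qPCR scaled by ploidy measures
#' expression per cell. Their quotient estimates the size of the numerator
#' transcriptome relative to the denominator one.
#'
#' @param per_cell_ratio Positive numeric vector.
#' @param per_transcriptome_ratio Positive numeric vector.
#' @return Numeric vector of relative size estimates.
#' @export
#' @examples
#' size_ratio(1.2, 1.5)  # 0.8
size_ratio <- function(per_cell_ratio, per_transcriptome_ratio) {
  check_positive(per_cell_ratio, "per_cell_ratio")
  check_positive(per_transcriptome_ratio, "per_transcriptome_ratio")
  per_cell_ratio / per_transcriptome_ratio
}

#' Classical one-sample t-test
#'
#' Two-sided one-sample t-test of a vector mean against a null value, with
#' `df = n - 1`. Degenerate inputs are handled explicitly: with zero sample
#' variance the statistic is 0 (p = 1) when the common value equals the
#' null, otherwise infinite with p reported as 0 and a warning.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param null_value Null-hypothesis mean.
#' @return List with `t`, `df`, `p_two_sided`.
#' @export
#' @examples
#' one_sample_t(c(0.8, 0.9, 1.6, 0.9, 1.2, 0.8), 1.5)
one_sample_t <- function(values, null_value) {
  if (length(values) < 2) stop_invalid("need at least two values")
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  m <- mean(values)
  stderr <- sd(values) / sqrt(length(values))
  # same degeneracy guard as stats::t.test, handled instead of erroring
  if (stderr < 10 * .Machine$double.eps * max(1, abs(m))) {
    if (isTRUE(all.equal(m, null_value))) {
      return(list(t = 0, df = length(values) - 1L, p_two_sided = 1))
    }
    warning("zero sample variance with mean != null; p reported as 0")
    return(list(t = sign(m - null_value) * Inf,
                df = length(values) - 1L, p_two_sided = 0))
  }
  ht <- t.test(values, mu = null_value)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = unname(ht$p.value))
}

#' Outlier screen by Tukey fences
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` where the quartiles
#' are Tukey hinges (medians of the lower and upper halves, with the median
#' included in both halves for odd n, as computed by [stats::fivenum()]).
#'
#' @param values Numeric vector, `n >= 4`.
#' @return Logical vector: `TRUE` marks an outlier.
#' @export
#' @examples
#' tukey_outliers(c(0.8, 0.9, 1.6, 0.9, 1.2, 0.8))  # none flagged
tukey_outliers <- function(values) {
  if (length(values) < 4) stop_invalid("need at least four values")
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  hinges <- fivenum(values)[c(2, 4)]
  iqr <- hinges[2] - hinges[1]
  values < hinges[1] - 1.5 * iqr | values > hinges[2] + 1.5 * iqr
}

#' Per-gene transcriptome-size table from ratio columns
#'
#' Composes [per_cell_ratio()] and [size_ratio()] for a panel of target
#' genes whose per-genome (qPCR) and per-transcriptome (RNA-seq) ratios are
#' already known — e.g. taken from a published table.
#'
#' @param gene Character vector of gene names.
#' @param per_genome Positive numeric vector of genome-normalized qPCR
#'   ratios (numerator/denominator).
#' @param per_transcriptome Positive numeric vector of FPKM ratios.
#' @param numerator_ploidy,denominator_ploidy Ploidies of the compared
#'   genomotypes.
#' @return `data.frame` with columns `gene`, `per_genome`, `per_cell`,
#'   `per_transcriptome`, `size`.
#' @export
size_table_from_ratios <- function(gene, per_genome, per_transcriptome,
                                   numerator_ploidy = 3,
                                   denominator_ploidy = 2) {
  stopifnot(length(gene) == length(per_genome),
            length(gene) == length(per_transcriptome))
  cell <- per_cell_ratio(per_genome, numerator_ploidy, denominator_ploidy)
  data.frame(gene = as.character(gene),
             per_genome = per_genome,
             per_cell = cell,
             per_transcriptome = per_transcriptome,
             size = size_ratio(cell, per_transcriptome),
             stringsAsFactors = FALSE)
}

#' Estimate relative transcriptome size from qPCR and RNA-seq data
#'
#' For each target gene: (1) estimate the genome-normalized expression
#' ratio with [livak_per_genome()]; (2) scale to a per-cell ratio by the
#' ploidy quotient; (3) divide by the per-transcriptome (FPKM) ratio from
#' the RNA-seq tables. Each gene yields an independent estimate of the
#' numerator transcriptome's size relative to the denominator's. The
#' aggregate reports the mean and SD of the per-gene estimates, one-sample
#' t-tests against the genome-wide dosage-effect expectation
#' (`ploidy ratio`, 1.5 for PAA/PA) and the dosage-compensation expectation
#' (1.0), and a Tukey-fence outlier screen.
#'
#' @param qpcr Long qPCR `data.frame`.
#' @param rnaseq_num,rnaseq_den `expression_table`s of the numerator and
#'   denominator genomotypes (e.g. liv-PAA and liv-PA).
#' @param target_genes Character vector of cDNA-assayed target genes; all
#'   must be present with nonzero denominator abundance in the RNA-seq
#'   tables.
#' @param reference_targets gDNA-assayed reference genes.
#' @param numerator_genomotype,denominator_genomotype Genomotype labels;
#'   ploidies are derived from the labels.
#' @return An object of class `transcriptome_size_estimate`: list with
#'   `table` (per-gene ratios incl. `sd_per_genome` and `outlier`),
#'   `mean_size`, `sd_size`, `t_vs_dosage_effect`, `t_vs_compensation`,
#'   `outlier_flags`, `ploidy_ratio`.
#' @export
estimate_transcriptome_size <- function(qpcr, rnaseq_num, rnaseq_den,
                                        target_genes, reference_targets,
                                        numerator_genomotype = "PAA",
                                        denominator_genomotype = "PA") {
  gt_num <- as_genomotype(numerator_genomotype)
  gt_den <- as_genomotype(denominator_genomotype)
  missing_num <- setdiff(target_genes, rnaseq_num$gene_id)
  missing_den <- setdiff(target_genes, rnaseq_den$gene_id)
  if (length(missing_num) || length(missing_den)) {
    stop_invalid("target gene(s) absent from RNA-seq table(s): ",
                 paste(unique(c(missing_num, missing_den)), collapse = ", "))
  }
  fpkm_num <- rnaseq_num$fpkm[match(target_genes, rnaseq_num$gene_id)]
  fpkm_den <- rnaseq_den$fpkm[match(target_genes, rnaseq_den$gene_id)]
  if (any(fpkm_den <= 0)) {
    stop_invalid("zero denominator abundance for target gene(s): ",
                 paste(target_genes[fpkm_den <= 0], collapse = ", "))
  }
  livak <- lapply(target_genes, function(g) {
    livak_per_genome(qpcr, g, reference_targets,
                     numerator_genomotype = gt_num$label,
                     denominator_genomotype = gt_den$label)
  })
  per_genome <- vapply(livak, `[[`, numeric(1), "ratio_per_genome")
  sd_per_genome <- vapply(livak, `[[`, numeric(1), "sd_ratio")
  tab <- size_table_from_ratios(target_genes, per_genome,
                                fpkm_num / fpkm_den,
                                numerator_ploidy = gt_num$ploidy,
                                denominator_ploidy = gt_den$ploidy)
  tab$sd_per_genome <- sd_per_genome
  ploidy_ratio <- gt_num$ploidy / gt_den$ploidy
  flags <- tukey_outliers(tab$size)
  tab$outlier <- flags
  structure(
    list(table = tab,
         mean_size = mean(tab$size),
         sd_size = sd(tab$size),
         t_vs_dosage_effect = one_sample_t(tab$size, ploidy_ratio),
         t_vs_compensation = one_sample_t(tab$size, 1.0),
         outlier_flags = setNames(flags, tab$gene),
         ploidy_ratio = ploidy_ratio),
    class = "transcriptome_size_estimate"
  )
}

#' @export
print.transcriptome_size_estimate <- function(x, ...) {
  cat(sprintf("relative transcriptome size from %d gene estimates\n",
              nrow(x$table)))
  print(cbind(x$table[c("gene", "per_genome", "per_cell",
                        "per_transcriptome", "size")],
              row.names = NULL), digits = 3)
  cat(sprintf("mean size %.2f (SD %.2f)\n", x$mean_size, x$sd_size))
  cat(sprintf("t vs dosage effect (%.1f): t = %.2f, df = %d, p = %.4g\n",
              x$ploidy_ratio, x$t_vs_dosage_effect$t,
              x$t_vs_dosage_effect$df, x$t_vs_dosage_effect$p_two_sided))
  cat(sprintf("t vs compensation (1.0): t = %.2f, df = %d, p = %.4g\n",
              x$t_vs_compensation$t, x$t_vs_compensation$df,
              x$t_vs_compensation$p_two_sided))
  if (any(x$outlier_flags)) {
    cat("outliers:", paste(names(x$outlier_flags)[x$outlier_flags],
                           collapse = ", "), "\n")
  } else {
    cat("no Tukey-fence outliers\n")
  }
  invisible(x)
}

#' Published six-gene liver panel ratios
#'
#' The published PAA/PA liver panel for *Squalius alburnoides*: per-genome
#' qPCR ratios (mean and SD over five biological replicates), the published
#' per-cell and relative-size columns (rounded to one decimal as printed),
#' and the per-transcriptome RPKM ratios from the liver RNA-seq libraries.
#' Shipped as plain TSV in `extdata`; useful for reproducing the published
#' size arithmetic with [size_table_from_ratios()].
#'
#' @return `data.frame` with columns `gene`, `per_genome`,
#'   `sd_per_genome`, `per_cell_published`, `per_transcriptome`,
#'   `size_published`.
#' @export
published_liver_ratios <- function() {
  path <- system.file("extdata", "salburnoides_liver_panel.tsv",
                      package = "ploidosage", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
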