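#' Configuration for the synthetic four-genomotype study generator
#'
#' Defines the conditions of a simulated diploid/triploid comparison
#' mirroring the study design: four RNA-seq libraries (PP, AA, PA, PAA, one
#' library per genomotype), and a qPCR plate with five biological times
#' three technical replicates per genomotype over six cDNA targets and
#' three gDNA references.
#'
#' Genes are split into an exact mid-parent (additive) fraction and a
#' remainder whose true PAA/PA fold change is drawn inside an assigned
#' dosage-response interval according to `class_mixture`. Mixture fractions
#' are interpreted as fractions of the non-additive genes and may also name
#' `DE_up` / `DE_down` (strong, significance-scale fold changes); any
#' remainder is drawn uniformly (in log2) from the similar-expression band.
#'
#' @param n_genes Number of genes.
#' @param class_mixture Named fractions over
#'   `{I, II, III, IV, DE_up, DE_down}` summing to at most 1.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters (natural
#'   log) of the AA parent's FPKM distribution. Defaults `2` and `1.5`
#'   give a median around 7 FPKM with a realistic dynamic range.
#' @param parental_divergence_log2_sd SD of the log2 offset between the PP
#'   and AA parents (between-species expression divergence).
#' @param additive_fraction Fraction of genes built as exact mid-parent
#'   hybrids.
#' @param measurement_log2_sd SD of the multiplicative log2-normal
#'   measurement noise applied independently to every gene in every
#'   library, after construction.
#' @param library_sizes Named vector of total mapped fragments per
#'   genomotype library.
#' @param qpcr List with `n_biological`, `n_technical`, `cq_noise_sd`
#'   (additive Gaussian noise per well, in cycles), and
#'   `true_per_genome_ratios` (named positive vector per target gene;
#'   defaults mirror the published liver panel magnitudes).
#' @param seed Integer; the generator is fully reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 20000,
    class_mixture = c(I = 0.45, II = 0.17, III = 0.34, IV = 0.04),
    baseline_log_mean = 2,
    baseline_log_sd = 1.5,
    parental_divergence_log2_sd = 1,
    additive_fraction = 0.36,
    measurement_log2_sd = 0.2,
    library_sizes = c(PP = 2e7, AA = 2e7, PA = 2e7, PAA = 2e7),
    qpcr = list(n_biological = 5, n_technical = 3, cq_noise_sd = 0.15,
                true_per_genome_ratios = c(rpl8 = 0.8, eef1a = 0.8,
                                           actb2 = 0.6, rpsa = 0.9,
                                           pabpc1a = 0.8, rpl35 = 0.8)),
    seed = 1L) {
  stopifnot(n_genes >= 1)
  allowed <- c("I", "II", "III", "IV", "DE_up", "DE_down")
  if (is.null(names(class_mixture)) ||
      !all(names(class_mixture) %in% allowed)) {
    stop_invalid("'class_mixture' names must be among: ",
                 paste(allowed, collapse = ", "))
  }
  if (any(class_mixture < 0) || any(class_mixture > 1)) {
    stop_invalid("'class_mixture' fractions must lie in [0, 1]")
  }
  if (sum(class_mixture) > 1 + 1e-12) {
    stop_invalid("'class_mixture' fractions must sum to at most 1")
  }
  if (baseline_log_sd < 0 || parental_divergence_log2_sd < 0 ||
      measurement_log2_sd < 0 || qpcr$cq_noise_sd < 0) {
    stop_invalid("all noise standard deviations must be nonnegative")
  }
  if (additive_fraction < 0 || additive_fraction > 1) {
    stop_invalid("'additive_fraction' must lie in [0, 1]")
  }
  if (any(library_sizes <= 0)) {
    stop_invalid("'library_sizes' must be positive")
  }
  if (qpcr$n_technical < 1) stop_invalid("'n_technical' must be >= 1")
  if (qpcr$n_biological < 1) stop_invalid("'n_biological' must be >= 1")
  if (any(qpcr$true_per_genome_ratios <= 0)) {
    stop_invalid("'true_per_genome_ratios' must be positive")
  }
  structure(
    list(n_genes = as.integer(n_genes), class_mixture = class_mixture,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         parental_divergence_log2_sd = parental_divergence_log2_sd,
         additive_fraction = additive_fraction,
         measurement_log2_sd = measurement_log2_sd,
         library_sizes = library_sizes, qpcr = qpcr,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# internal: draw one true fold change inside the interval of each label
draw_true_fold <- function(labels, config) {
  b <- c(0.75, 1.25, 1.75)  # canonical class bounds of the study design
  band <- 2^c(-1, 1)
  n <- length(labels)
  fold <- numeric(n)
  pick <- function(lab) labels == lab
  fold[pick("I")] <- runif(sum(pick("I")), b[1], b[2])
  fold[pick("II")] <- runif(sum(pick("II")), b[2], b[3])
  fold[pick("III")] <- runif(sum(pick("III")), band[1], b[1])
  fold[pick("IV")] <- runif(sum(pick("IV")), b[3], band[2])
  fold[pick("DE_up")] <- 2^runif(sum(pick("DE_up")), 1.2, 3)
  fold[pick("DE_down")] <- 2^-runif(sum(pick("DE_down")), 1.2, 3)
  fold[pick("SE_other")] <- 2^runif(sum(pick("SE_other")), -1, 1)
  fold
}

#' Simulate four-genomotype expression tables with known ground truth
#'
#' Builds per-gene FPKM abundances for the PP, AA, PA and PAA libraries:
#' AA is log-normal, PP is AA shifted by a Normal log2 divergence, PA is
#' the exact mid-parent of PP and AA, and PAA is either the exact additive
#' expectation (`PP/2 + AA`) for the additive fraction or `PA` times a
#' true fold change drawn inside the assigned class interval. Log2-normal
#' measurement noise is applied last, independently per gene and library.
#' Integer fragment counts are derived from the noisy abundances by
#' inverse-FPKM rounding against the configured library sizes; the stored
#' abundance keeps the exact continuous value used by the ratio analyses
#' (the rounded count is a derived, quantized view of it).
#'
#' @param config A [simulation_config()].
#' @return List with `tables` (named list of `expression_table`s for PP,
#'   AA, PA, PAA), `truth` (`data.frame` with `gene_id`, `label` — class
#'   I–IV, `DE_up`, `DE_down`, `SE_other` or `additive` — and `true_fold`,
#'   the noiseless PAA/PA fold change), and `config`.
#' @export
simulate_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  lengths <- pmax(200L, as.integer(round(rlnorm(n, log(1500), 0.6))))

  aa <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  pp <- aa * 2^rnorm(n, 0, config$parental_divergence_log2_sd)

  n_add <- round(config$additive_fraction * n)
  is_additive <- seq_len(n) %in% sample.int(n, n_add)
  labels <- rep("additive", n)
  rest <- which(!is_additive)
  if (length(rest)) {
    mix <- config$class_mixture
    probs <- c(mix, SE_other = max(0, 1 - sum(mix)))
    labels[rest] <- sample(names(probs), length(rest), replace = TRUE,
                           prob = probs)
  }
  true_fold <- rep(NA_real_, n)
  pa <- (pp + aa) / 2
  paa <- numeric(n)
  paa[is_additive] <- pp[is_additive] / 2 + aa[is_additive]
  non_add <- !is_additive
  true_fold[non_add] <- draw_true_fold(labels[non_add], config)
  paa[non_add] <- pa[non_add] * true_fold[non_add]
  true_fold[is_additive] <- paa[is_additive] / pa[is_additive]

  abundances <- list(PP = pp, AA = aa, PA = pa, PAA = paa)
  tables <- lapply(names(abundances), function(g) {
    noisy <- abundances[[g]] *
      2^rnorm(n, 0, config$measurement_log2_sd)
    lib <- config$library_sizes[[g]]
    counts <- round(noisy * lengths * lib / 1e9)
    expression_table(gene_id, fpkm = noisy, length = lengths,
                     count = counts,
                     library_label = paste0("sim-", g), genomotype = g)
  })
  names(tables) <- names(abundances)
  list(tables = tables,
       truth = data.frame(gene_id = gene_id, label = labels,
                          true_fold = true_fold,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Simulate a genome-normalized qPCR plate
#'
#' Emulates the co-extracted cDNA/gDNA assay: for each biological sample a
#' template-input offset shifts every well (cancelled by the genomic
#' normalization), gDNA reference wells sit at target-specific baselines,
#' and cDNA target wells are placed so that the expected `2^-ddCq` of the
#' numerator vs denominator genomotype equals the configured true
#' per-genome ratio. Gaussian Cq noise is added independently per well.
#'
#' @param config A [simulation_config()].
#' @param numerator_genomotype,denominator_genomotype Genomotype labels of
#'   the two compared groups.
#' @return Long qPCR `data.frame` (columns `sample_id`, `genomotype`,
#'   `target`, `template`, `replicate`, `cq`).
#' @export
simulate_qpcr <- function(config = simulation_config(),
                          numerator_genomotype = "PAA",
                          denominator_genomotype = "PA") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  qc <- config$qpcr
  targets <- names(qc$true_per_genome_ratios)
  refs <- c("rpl8", "eef1a", "actb2")
  ref_base <- setNames(c(21, 22, 23), refs)
  target_delta <- setNames(3 + 0.6 * (seq_along(targets) - 1), targets)
  genos <- c(denominator_genomotype, numerator_genomotype)
  rows <- list()
  for (g in genos) {
    for (b in seq_len(qc$n_biological)) {
      sid <- sprintf("%s_%d", g, b)
      offset <- rnorm(1, 0, 0.3)  # template input variation
      for (r in refs) {
        cq <- ref_base[[r]] + offset +
          rnorm(qc$n_technical, 0, qc$cq_noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, genomotype = g, target = r, template = "gdna",
          replicate = seq_len(qc$n_technical), cq = cq,
          stringsAsFactors = FALSE)
      }
      for (t in targets) {
        shift <- if (g == numerator_genomotype)
          -log2(qc$true_per_genome_ratios[[t]]) else 0
        cq <- mean(ref_base) + offset + target_delta[[t]] + shift +
          rnorm(qc$n_technical, 0, qc$cq_noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, genomotype = g, target = t, template = "cdna",
          replicate = seq_len(qc$n_technical), cq = cq,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated study to disk
#'
#' Writes the four expression TSVs, the qPCR CSV and the ground-truth TSV
#' produced by [simulate_expression()] and [simulate_qpcr()] into a
#' directory. Output is byte-identical for identical config and seed.
#'
#' @param sim Result of [simulate_expression()].
#' @param qpcr Result of [simulate_qpcr()] (optional).
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_simulation <- function(sim, qpcr = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (g in names(sim$tables)) {
    p <- file.path(outdir, sprintf("expression_%s.tsv", g))
    write_expression_tsv(sim$tables[[g]], p)
    paths[g] <- p
  }
  truth_path <- file.path(outdir, "truth.tsv")
  write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["truth"] <- truth_path
  if (!is.null(qpcr)) {
    qpcr_path <- file.path(outdir, "qpcr.csv")
    write_qpcr_csv(qpcr, qpcr_path)
    paths["qpcr"] <- qpcr_path
  }
  invisible(paths)
}
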