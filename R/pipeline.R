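#' Run the full dosage-response pipeline
#'
#' Composes the four analysis stages on whatever inputs are supplied, in
#' the canonical triploid-vs-diploid orientation (PAA as numerator, PA as
#' denominator):
#' \describe{
#'   \item{profile}{ratio profile PAA/PA with sign counts, median and the
#'     chi-square balance test (needs `PAA` and `PA`);}
#'   \item{classify}{SE thresholding, dosage classes and — when both
#'     tables carry counts — DE calling with dependent-test FDR;}
#'   \item{additivity}{observed vs mid-parent expected expression for each
#'     available hybrid (needs `PP` and `AA`);}
#'   \item{tsize}{relative transcriptome size (needs `qpcr` plus target /
#'     reference gene panels present in the PAA and PA tables).}
#' }
#' A stage whose inputs are missing is skipped with a logged reason;
#' stages are otherwise independent. Per-stage TSVs, a consolidated JSON
#' summary and a run manifest (file digests, config hash, seed, record
#' counts) are written to `outdir`.
#'
#' @param inputs Named list: any of `PP`, `AA`, `PA`, `PAA`
#'   (`expression_table` objects or TSV paths) and `qpcr` (data frame or
#'   CSV path).
#' @param config An [analysis_config()].
#' @param outdir Output directory.
#' @param target_genes,reference_targets Gene panels for the tsize stage.
#' @param quiet Suppress stage-boundary messages.
#' @return Invisibly, a list with `stages` (per-stage results or skip
#'   reasons), `summary` (the JSON-ready summary list) and `manifest`.
#' @export
run_full_pipeline <- function(inputs, config = analysis_config(),
                              outdir = tempfile("ploidosage_run_"),
                              target_genes = NULL,
                              reference_targets = c("rpl8", "eef1a",
                                                    "actb2"),
                              quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  tables <- list()
  for (g in c("PP", "AA", "PA", "PAA")) {
    if (!is.null(inputs[[g]])) {
      tab <- inputs[[g]]
      if (is.character(tab)) {
        tab <- read_expression_tsv(tab, genomotype = g)
      }
      bad <- validate_table(tab)
      if (length(bad)) {
        stop("stage input: table ", g, " is invalid: ", bad[1],
             call. = FALSE)
      }
      tables[[g]] <- tab
    }
  }
  qpcr <- inputs$qpcr
  if (is.character(qpcr)) qpcr <- read_qpcr_csv(qpcr)

  stages <- list()
  summary_out <- list()
  outputs <- character(0)

  write_stage <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
  }

  # -- profile ---------------------------------------------------------
  if (!is.null(tables$PAA) && !is.null(tables$PA)) {
    say("stage profile: PAA vs PA")
    prof <- ratio_profile(tables$PAA, tables$PA, config)
    ps <- summarize_profile(prof)
    chi <- chi_square_goodness(ps$n_negative, ps$n_positive)
    stages$profile <- list(records = prof, summary = ps, chi_square = chi)
    write_stage(prof[c("gene_id", "fold_change", "log2_ratio")],
                "profile_PAA_vs_PA.tsv")
    summary_out$profile <- list(
      n_genes = nrow(prof), n_dropped = attr(prof, "n_dropped"),
      n_higher = ps$n_positive, n_lower = ps$n_negative,
      n_zero = ps$n_zero, median_log2 = ps$median_log2,
      chi_square = chi)
    say("  %d genes (%d dropped), lower %d vs higher %d",
        nrow(prof), attr(prof, "n_dropped"), ps$n_negative, ps$n_positive)
  } else {
    stages$profile <- list(skipped = "requires PAA and PA tables")
    say("stage profile: skipped (%s)", stages$profile$skipped)
  }

  # -- classify --------------------------------------------------------
  if (!is.null(stages$profile$records)) {
    say("stage classify")
    prof <- stages$profile$records
    counts <- NULL
    if (!all(is.na(tables$PAA$count)) && !all(is.na(tables$PA$count))) {
      ia <- match(prof$gene_id, tables$PAA$gene_id)
      ib <- match(prof$gene_id, tables$PA$gene_id)
      ca <- tables$PAA$count[ia]
      cb <- tables$PA$count[ib]
      ok <- !is.na(ca) & !is.na(cb)
      counts <- data.frame(gene_id = prof$gene_id[ok], count_a = ca[ok],
                           count_b = cb[ok], stringsAsFactors = FALSE)
      prof <- prof[ok, , drop = FALSE]
    }
    cls <- classify_dosage(prof, config, counts = counts,
                           libsize_a = sum(tables$PAA$count, na.rm = TRUE),
                           libsize_b = sum(tables$PA$count, na.rm = TRUE))
    tl <- tally(cls)
    stages$classify <- list(records = cls, tally = tl)
    write_stage(cls, "classification_PAA_vs_PA.tsv")
    summary_out$classify <- list(
      n_total = tl$n_total, n_se = tl$n_se, n_de = tl$n_de,
      per_class = as.list(tl$per_class),
      per_de_group = as.list(tl$per_de_group),
      percentages = tl$percentages)
    say("  SE %d of %d; DE %d", tl$n_se, tl$n_total, tl$n_de)
  } else {
    stages$classify <- list(skipped = "requires the profile stage")
    say("stage classify: skipped (%s)", stages$classify$skipped)
  }

  # -- additivity ------------------------------------------------------
  if (!is.null(tables$PP) && !is.null(tables$AA) &&
      (!is.null(tables$PA) || !is.null(tables$PAA))) {
    stages$additivity <- list()
    summary_out$additivity <- list()
    for (h in intersect(c("PA", "PAA"), names(tables))) {
      say("stage additivity: %s vs mid-parent", h)
      rec <- additivity_profile(tables$PP, tables$AA, tables[[h]],
                                genomotype = h)
      tl <- additivity_tally(rec)
      stages$additivity[[h]] <- list(records = rec, tally = tl)
      write_stage(rec, sprintf("additivity_%s.tsv", h))
      summary_out$additivity[[h]] <- list(
        counts = as.list(tl$counts),
        percentages = as.list(tl$percentages),
        chi_square_non_additive = tl$chi_square_non_additive)
      say("  %s%% additive",
          format(tl$percentages[["additive"]]))
    }
  } else {
    stages$additivity <-
      list(skipped = "requires PP, AA and at least one hybrid table")
    say("stage additivity: skipped (%s)", stages$additivity$skipped)
  }

  # -- tsize -----------------------------------------------------------
  if (!is.null(qpcr) && !is.null(tables$PAA) && !is.null(tables$PA) &&
      !is.null(target_genes)) {
    say("stage tsize: %d target genes", length(target_genes))
    est <- estimate_transcriptome_size(
      qpcr, tables$PAA, tables$PA, target_genes, reference_targets)
    stages$tsize <- est
    write_stage(est$table, "transcriptome_size.tsv")
    summary_out$tsize <- list(
      per_gene = est$table,
      mean_size = est$mean_size, sd_size = est$sd_size,
      t_vs_dosage_effect = est$t_vs_dosage_effect,
      t_vs_compensation = est$t_vs_compensation,
      outlier_flags = as.list(est$outlier_flags))
    say("  mean size %.2f (SD %.2f)", est$mean_size, est$sd_size)
  } else {
    stages$tsize <-
      list(skipped = "requires qPCR data, PAA/PA tables and target genes")
    say("stage tsize: skipped (%s)", stages$tsize$skipped)
  }

  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary_out, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  outputs[["summary.json"]] <- summary_path

  manifest <- build_manifest(config, outputs, stages)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(stages = stages, summary = summary_out,
                 manifest = manifest, outdir = outdir))
}

# internal: run manifest with config hash and output digests
build_manifest <- function(config, outputs, stages) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  skipped <- names(Filter(function(s) !is.null(s$skipped), stages))
  counts <- lapply(stages, function(s) {
    if (!is.null(s$records)) nrow(s$records) else NULL
  })
  list(
    tool = "ploidosage",
    version = as.character(packageVersion("ploidosage")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(tools::md5sum(unlist(outputs))),
    skipped_stages = if (length(skipped)) skipped else list(),
    record_counts = Filter(Negate(is.null), counts)
  )
}
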