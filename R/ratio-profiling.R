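#' Pairwise fold-change profile between two expression tables
#'
#' Divides each gene's abundance in the numerator library by its abundance
#' in the denominator library, yielding one fold change and log2 ratio per
#' shared gene. Zero abundances are handled by the configuration's zero
#' policy: under `"exclude"` a gene with zero abundance in either library is
#' dropped (the number dropped is attached as attribute `n_dropped`); under
#' `"pseudocount"` both abundances are incremented before division.
#'
#' @param numerator,denominator `expression_table` objects sharing a
#'   nonempty set of gene ids.
#' @param config An [analysis_config()].
#' @return A `data.frame` with columns `gene_id`, `numerator_abundance`,
#'   `denominator_abundance`, `fold_change`, `log2_ratio`, one row per
#'   admitted shared gene; attributes `n_dropped`, `numerator_label`,
#'   `denominator_label`.
#' @export
#' @examples
#' a <- expression_table(c("g1", "g2"), c(4, 1), genomotype = "PAA")
#' b <- expression_table(c("g1", "g2"), c(2, 2), genomotype = "PA")
#' ratio_profile(a, b)
ratio_profile <- function(numerator, denominator,
                          config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  shared <- intersect(numerator$gene_id, denominator$gene_id)
  if (length(shared) == 0) {
    stop_invalid("the two tables share no gene ids")
  }
  num <- numerator$fpkm[match(shared, numerator$gene_id)]
  den <- denominator$fpkm[match(shared, denominator$gene_id)]
  n_dropped <- 0L
  if (config$zero_policy == "exclude") {
    keep <- num > 0 & den > 0
    n_dropped <- sum(!keep)
    shared <- shared[keep]
    num <- num[keep]
    den <- den[keep]
    if (length(shared) == 0) {
      stop_invalid("no gene has nonzero abundance in both libraries")
    }
  } else {
    num <- num + config$pseudocount
    den <- den + config$pseudocount
    if (any(den == 0)) {
      stop_invalid("zero denominator abundance with pseudocount 0")
    }
  }
  out <- data.frame(gene_id = shared,
                    numerator_abundance = num,
                    denominator_abundance = den,
                    fold_change = num / den,
                    log2_ratio = log2(num / den),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "numerator_label") <- attr(numerator, "library_label")
  attr(out, "denominator_label") <- attr(denominator, "library_label")
  out
}

#' Summarize a ratio profile
#'
#' Orders the log2 ratios ascending (the "crescent curve" view of a
#' comparative profile) and counts ratios by sign; the median tells whether
#' most transcripts are lower or higher expressed in the numerator library.
#'
#' @param records A ratio-profile `data.frame` from [ratio_profile()], or
#'   any data frame with a `log2_ratio` column.
#' @return An object of class `profile_summary`: list with `n_positive`,
#'   `n_negative`, `n_zero`, `median_log2`, `ordered_log2`.
#' @export
summarize_profile <- function(records) {
  if (is.data.frame(records)) records <- records$log2_ratio
  if (is.null(records) || length(records) == 0) {
    stop_invalid("empty ratio profile")
  }
  if (any(!is.finite(records))) {
    stop_invalid("log2 ratios must be finite")
  }
  ordered <- sort(records)
  structure(
    list(n_positive = sum(records > 0),
         n_negative = sum(records < 0),
         n_zero = sum(records == 0),
         median_log2 = median(ordered),
         ordered_log2 = ordered),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  n <- length(x$ordered_log2)
  cat(sprintf("ratio profile of %d genes\n", n))
  cat(sprintf("  higher in numerator (log2 > 0): %d (%s%%)\n", x$n_positive,
              format(round_half_away(100 * x$n_positive / n))))
  cat(sprintf("  lower  in numerator (log2 < 0): %d (%s%%)\n", x$n_negative,
              format(round_half_away(100 * x$n_negative / n))))
  if (x$n_zero > 0) cat(sprintf("  exactly equal: %d\n", x$n_zero))
  cat(sprintf("  median log2 ratio: %.4f\n", x$median_log2))
  invisible(x)
}

#' Chi-square test of a lower/higher count split against 50:50
#'
#' One-degree-of-freedom goodness-of-fit test, without continuity
#' correction, of the observed numbers of lower and higher expressed
#' transcripts against an equal split.
#'
#' @param n_lower,n_higher Nonnegative integer counts; not both zero.
#' @return List with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_goodness(60, 40)  # statistic 4, p ~ 0.0455
chi_square_goodness <- function(n_lower, n_higher) {
  if (!is.numeric(n_lower) || !is.numeric(n_higher) ||
      n_lower < 0 || n_higher < 0) {
    stop_invalid("counts must be nonnegative")
  }
  if (n_lower + n_higher == 0) stop_invalid("both counts are zero")
  ht <- suppressWarnings(
    chisq.test(c(n_lower, n_higher), p = c(0.5, 0.5))
  )
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Chi-square test of homogeneity on a 2x2 contingency table
#'
#' One-degree-of-freedom contingency chi-square without continuity
#' correction. Rows are two comparisons, columns the lower/higher counts,
#' so the test asks whether the lower-vs-higher balance differs between the
#' comparisons.
#'
#' @param a,b Lower and higher counts of the first comparison.
#' @param c,d Lower and higher counts of the second comparison.
#' @return List with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_2x2(20, 10, 10, 20)  # statistic 6.667
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (!is.numeric(counts) || any(counts < 0)) {
    stop_invalid("all four counts must be nonnegative")
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_invalid("every row and column marginal must be positive")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
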