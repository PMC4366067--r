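#' Similar-expression test on a fold change
#'
#' A gene is similarly expressed (SE) between two libraries when its fold
#' change differs less than `2^se_log2_threshold`-fold in either direction,
#' i.e. `|log2(fold_change)| < se_log2_threshold`, with strict inequality
#' (a gene at exactly twofold is not SE under the default threshold).
#'
#' @param fold_change Positive numeric vector.
#' @param config An [analysis_config()].
#' @return Logical vector.
#' @export
#' @examples
#' classify_similarity(c(1, 1.99, 2))
classify_similarity <- function(fold_change, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.numeric(fold_change) || any(!is.finite(fold_change)) ||
      any(fold_change <= 0)) {
    stop_invalid("'fold_change' must be positive and finite")
  }
  abs(log2(fold_change)) < config$se_log2_threshold
}

#' Dosage-response class of a similarly expressed gene
#'
#' Partitions the SE fold-change band into four dosage-response classes for
#' a triploid/diploid comparison:
#' \describe{
#'   \item{I}{compensated — ratio about 1, `[0.75, 1.25]`;}
#'   \item{II}{dosage sensitive — ratio about 1.5, `(1.25, 1.75]`;}
#'   \item{III}{repressed beyond compensation — ratio below 0.75;}
#'   \item{IV}{overexpressed — ratio above 1.75.}
#' }
#' Boundary ties go to the inner classes (I is closed, II half-open), so a
#' gene printed exactly at a bound receives the more conservative
#' compensated/dosage-sensitive label. The bounds come from
#' `config$class_bounds`.
#'
#' @param fold_change Positive numeric vector; every element must satisfy
#'   [classify_similarity()] (contract error otherwise).
#' @param config An [analysis_config()].
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
#' @examples
#' assign_dosage_class(c(1, 1.5, 0.6, 1.8))
assign_dosage_class <- function(fold_change, config = analysis_config()) {
  se <- classify_similarity(fold_change, config)
  if (any(!se)) {
    stop_invalid("assign_dosage_class() called on non-SE fold change(s): ",
                 paste(format(fold_change[!se][seq_len(min(3, sum(!se)))]),
                       collapse = ", "))
  }
  b <- config$class_bounds
  cls <- ifelse(fold_change < b[1], "III",
         ifelse(fold_change <= b[2], "I",
         ifelse(fold_change <= b[3], "II", "IV")))
  factor(cls, levels = c("I", "II", "III", "IV"))
}

#' Two-library exact binomial test for differential expression
#'
#' Exact test of a gene's fragment counts in two libraries against the
#' null that fragments fall into library A with probability
#' `libsize_a / (libsize_a + libsize_b)`. The two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one
#' (the minimum-likelihood rule). With both counts zero there is no
#' evidence and p = 1.
#'
#' This is a deliberately simple single-library-per-condition engine for
#' count data without replication; it provides the raw p-values that the
#' dependent-test FDR step adjusts.
#'
#' @param count_a,count_b Nonnegative integer vectors of per-gene counts.
#' @param libsize_a,libsize_b Positive scalars: total mapped fragments of
#'   each library.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' de_exact_test(10, 0, 1e6, 1e6)  # 2 * 0.5^10
de_exact_test <- function(count_a, count_b, libsize_a, libsize_b) {
  check_positive(libsize_a, "libsize_a")
  check_positive(libsize_b, "libsize_b")
  if (any(count_a < 0) || any(count_b < 0) ||
      any(count_a != round(count_a)) || any(count_b != round(count_b))) {
    stop_invalid("counts must be nonnegative integers")
  }
  pr <- libsize_a / (libsize_a + libsize_b)
  mapply(function(a, b) {
    n <- a + b
    if (n == 0) return(1)
    probs <- dbinom(0:n, n, pr)
    # tolerance guards float ties between symmetric outcomes
    p <- sum(probs[probs <= probs[a + 1] * (1 + 1e-12)])
    min(1, p)
  }, count_a, count_b)
}

#' Dependent-test FDR adjustment (Benjamini-Yekutieli step-up)
#'
#' Adjusts raw p-values with the step-up procedure valid under arbitrary
#' dependence of the tests:
#' `q_(i) = min over j >= i of min(1, p_(j) * m * c(m) / j)` with
#' `c(m) = sum(1/k, k = 1..m)`. The harmonic factor `c(m)` makes the
#' q-values dominate the independence-assuming Benjamini-Hochberg ones.
#'
#' @param raw_p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in input order.
#' @export
#' @examples
#' fdr_adjust_dependent(c(0.01, 0.02, 0.03))  # all 0.055
fdr_adjust_dependent <- function(raw_p) {
  if (length(raw_p) == 0) stop_invalid("empty p-value list")
  if (any(is.na(raw_p)) || any(raw_p < 0) || any(raw_p > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  m <- length(raw_p)
  cm <- sum(1 / seq_len(m))
  ord <- order(raw_p)
  scaled <- raw_p[ord] * m * cm / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(scaled))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Full dosage-response classification of a ratio profile
#'
#' Applies the SE threshold and dosage classes to every gene of a ratio
#' profile and, when per-gene counts are available, calls differential
#' expression (DE) with the exact binomial test and the dependent-test FDR
#' correction. SE and DE are computed independently: a gene can be SE, DE,
#' both, or neither.
#'
#' @param ratios Ratio profile from [ratio_profile()] (numerator = triploid
#'   in the canonical PAA/PA comparison).
#' @param config An [analysis_config()].
#' @param counts Optional `data.frame` with columns `gene_id`, `count_a`
#'   (numerator library), `count_b` (denominator library).
#' @param libsize_a,libsize_b Optional library totals; default to the column
#'   sums of `counts`.
#' @return A `data.frame` with columns `gene_id`, `fold_change`,
#'   `log2_ratio`, `se_flag`, `dosage_class` (factor, `NA` for non-SE
#'   genes), and — when counts are given — `raw_p`, `fdr_q`, `de_flag`,
#'   `de_direction` (`"higher"`/`"lower"` in the numerator, else
#'   `"none"`).
#' @export
classify_dosage <- function(ratios, config = analysis_config(),
                            counts = NULL, libsize_a = NULL,
                            libsize_b = NULL) {
  stopifnot(is.data.frame(ratios),
            all(c("gene_id", "fold_change") %in% names(ratios)))
  fc <- ratios$fold_change
  se <- classify_similarity(fc, config)
  cls <- factor(rep(NA_character_, length(fc)),
                levels = c("I", "II", "III", "IV"))
  if (any(se)) cls[se] <- assign_dosage_class(fc[se], config)
  out <- data.frame(gene_id = ratios$gene_id,
                    fold_change = fc,
                    log2_ratio = log2(fc),
                    se_flag = se,
                    dosage_class = cls,
                    stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    stopifnot(all(c("gene_id", "count_a", "count_b") %in% names(counts)))
    if (is.null(libsize_a)) libsize_a <- sum(counts$count_a)
    if (is.null(libsize_b)) libsize_b <- sum(counts$count_b)
    idx <- match(out$gene_id, counts$gene_id)
    if (any(is.na(idx))) {
      stop_invalid("counts missing for gene(s): ",
                   paste(utils::head(out$gene_id[is.na(idx)], 3),
                         collapse = ", "))
    }
    raw_p <- de_exact_test(counts$count_a[idx], counts$count_b[idx],
                           libsize_a, libsize_b)
    fdr_q <- fdr_adjust_dependent(raw_p)
    de <- fdr_q <= config$fdr_alpha
    out$raw_p <- raw_p
    out$fdr_q <- fdr_q
    out$de_flag <- de
    out$de_direction <- ifelse(!de, "none",
                               ifelse(out$fold_change > 1, "higher", "lower"))
  }
  out
}

#' Tally dosage-response classes and differential-expression groups
#'
#' Aggregates a classification into the count/percentage layout of the
#' study's summary tables: SE genes per class as percentages of SE and of
#' all genes, and DE genes split into DEH (higher in the numerator) and DEL
#' (lower) as percentages of DE and of all genes. Class and group
#' percentages are rounded half away from zero to integers; the DE share of
#' the whole table is kept at one decimal.
#'
#' @param records Classification `data.frame` from [classify_dosage()].
#' @return An object of class `class_tally`: list with `n_total`, `n_se`,
#'   `n_de`, `per_class`, `per_de_group`, and a `percentages` sublist.
#' @export
tally <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("se_flag", "dosage_class") %in% names(records)))
  n_total <- nrow(records)
  n_se <- sum(records$se_flag)
  per_class <- table(factor(records$dosage_class[records$se_flag],
                            levels = c("I", "II", "III", "IV")))
  per_class <- setNames(as.integer(per_class), names(per_class))
  has_de <- "de_flag" %in% names(records)
  if (has_de) {
    de <- records$de_flag
    n_de <- sum(de)
    per_de_group <- c(DEH = sum(de & records$de_direction == "higher"),
                      DEL = sum(de & records$de_direction == "lower"))
  } else {
    n_de <- 0L
    per_de_group <- c(DEH = 0L, DEL = 0L)
  }
  pct <- list(
    se_of_total = round_half_away(100 * n_se / n_total),
    class_of_se = if (n_se > 0)
      round_half_away(100 * per_class / n_se) else per_class * NA_real_,
    class_of_total = round_half_away(100 * per_class / n_total),
    de_of_total = round_half_away(100 * n_de / n_total, 1),
    de_group_of_de = if (n_de > 0)
      round_half_away(100 * per_de_group / n_de) else per_de_group * NA_real_,
    de_group_of_total = round_half_away(100 * per_de_group / n_total, 2)
  )
  structure(
    list(n_total = n_total, n_se = n_se, n_de = n_de,
         per_class = per_class, per_de_group = per_de_group,
         percentages = pct),
    class = "class_tally"
  )
}

#' @export
print.class_tally <- function(x, ...) {
  cat(sprintf("%d genes; SE %d (%s%%); DE %d (%s%%)\n",
              x$n_total, x$n_se, format(x$percentages$se_of_total),
              x$n_de, format(x$percentages$de_of_total)))
  for (cl in names(x$per_class)) {
    cat(sprintf("  class %-3s %7d  (%2s%% of SE, %2s%% of total)\n", cl,
                x$per_class[[cl]],
                format(x$percentages$class_of_se[[cl]]),
                format(x$percentages$class_of_total[[cl]])))
  }
  if (x$n_de > 0) {
    for (g in names(x$per_de_group)) {
      cat(sprintf("  %s %9d  (%2s%% of DE)\n", g, x$per_de_group[[g]],
                  format(x$percentages$de_group_of_de[[g]])))
    }
  }
  invisible(x)
}
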