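#' Analysis configuration
#'
#' Bundles the thresholds of the dosage-response analysis. Defaults follow
#' the study design: similar expression (SE) means a fold change differing
#' less than twofold (`|log2(ratio)| < 1`), the SE band is partitioned at
#' 0.75, 1.25 and 1.75 into dosage-response classes, and differential
#' expression is called at FDR <= 0.05 with the dependent-test correction.
#'
#' @param se_log2_threshold Positive real; similar expression requires
#'   `|log2(fold change)|` strictly below this value. Default 1 (twofold).
#' @param class_bounds Three strictly increasing positive reals partitioning
#'   the SE fold-change band into classes III / I / II / IV
#'   (repressed / compensated / dosage sensitive / overexpressed).
#'   All bounds must lie inside the open SE band
#'   `(2^-se_log2_threshold, 2^se_log2_threshold)`.
#' @param fdr_alpha Significance cutoff on the FDR-adjusted q-value.
#' @param zero_policy How genes with zero abundance in either library enter
#'   ratio profiles: `"exclude"` drops them (default; keeps fold changes
#'   finite without inventing a pseudocount), `"pseudocount"` adds
#'   `pseudocount` to both abundances before dividing.
#' @param pseudocount Nonnegative real added under the pseudocount policy.
#' @param seed Integer seed recorded for reproducibility of any stochastic
#'   step run under this configuration.
#' @return An object of class `analysis_config` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$class_bounds
analysis_config <- function(se_log2_threshold = 1,
                            class_bounds = c(0.75, 1.25, 1.75),
                            fdr_alpha = 0.05,
                            zero_policy = c("exclude", "pseudocount"),
                            pseudocount = 0.5,
                            seed = 1L) {
  zero_policy <- match.arg(zero_policy)
  check_positive(se_log2_threshold, "se_log2_threshold")
  if (length(class_bounds) != 3 || any(class_bounds <= 0)) {
    stop_invalid("'class_bounds' must be three positive reals")
  }
  if (any(diff(class_bounds) <= 0)) {
    stop_invalid("'class_bounds' must be strictly increasing")
  }
  band <- 2^c(-se_log2_threshold, se_log2_threshold)
  if (any(class_bounds <= band[1]) || any(class_bounds >= band[2])) {
    stop_invalid("'class_bounds' must lie strictly inside the SE band (",
                 format(band[1]), ", ", format(band[2]), ")")
  }
  if (!is.numeric(fdr_alpha) || length(fdr_alpha) != 1 ||
      fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop_invalid("'fdr_alpha' must lie in (0, 1)")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    stop_invalid("'pseudocount' must be a nonnegative real")
  }
  structure(
    list(se_log2_threshold = se_log2_threshold,
         class_bounds = class_bounds,
         fdr_alpha = fdr_alpha,
         zero_policy = zero_policy,
         pseudocount = pseudocount,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mapping may set any subset of the [analysis_config()] arguments;
#' unset fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  fields <- yaml::read_yaml(path)
  if (is.null(fields)) fields <- list()
  allowed <- names(formals(analysis_config))
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown)) {
    stop_invalid("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(fields$class_bounds)) {
    fields$class_bounds <- as.numeric(unlist(fields$class_bounds))
  }
  do.call(analysis_config, fields)
}

#' Write an analysis configuration to a YAML file
#'
#' @param config An `analysis_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
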