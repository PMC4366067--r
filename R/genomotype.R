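#' Genomotype specification
#'
#' A genomotype labels the genome composition of an individual in a hybrid
#' polyploid complex: which parental haplomes (haploid genome complements) it
#' carries and in how many copies. In the *Squalius alburnoides* complex the
#' haplomes are P (*S. pyrenaicus*) and A (the *Anaecypris hispanica*-like
#' ancestor), and the common genomotypes are PP, AA, PA (diploid) and PAA
#' (triploid).
#'
#' @param label Character scalar naming the genomotype. If `haplome_copies`
#'   is omitted, the label is parsed letter by letter, so `"PAA"` means one P
#'   copy and two A copies.
#' @param haplome_copies Optional named integer vector of copy counts per
#'   haplome symbol, e.g. `c(P = 1, A = 2)`.
#' @return An object of class `genomotype`: a list with `label`,
#'   `haplome_copies` (named integer vector) and `ploidy` (sum of copies).
#' @export
#' @examples
#' genomotype("PAA")
#' genomotype("PA")$ploidy
genomotype <- function(label, haplome_copies = NULL) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    stop_invalid("'label' must be a nonempty character scalar")
  }
  if (is.null(haplome_copies)) {
    letters_seen <- strsplit(label, "")[[1]]
    if (!all(grepl("^[A-Za-z]$", letters_seen))) {
      stop_invalid("genomotype label must contain only haplome letters")
    }
    tab <- table(letters_seen)
    haplome_copies <- setNames(as.integer(tab), names(tab))
  }
  if (is.null(names(haplome_copies)) || any(!nzchar(names(haplome_copies)))) {
    stop_invalid("'haplome_copies' must be a named vector")
  }
  haplome_copies <- setNames(as.integer(haplome_copies), names(haplome_copies))
  if (any(is.na(haplome_copies)) || any(haplome_copies < 0)) {
    stop_invalid("haplome copy counts must be nonnegative integers")
  }
  ploidy <- sum(haplome_copies)
  if (ploidy < 1) {
    stop_invalid("at least one haplome must have copy count >= 1")
  }
  structure(
    list(label = label, haplome_copies = haplome_copies, ploidy = ploidy),
    class = "genomotype"
  )
}

#' @export
print.genomotype <- function(x, ...) {
  copies <- paste(sprintf("%s=%d", names(x$haplome_copies), x$haplome_copies),
                  collapse = ", ")
  cat(sprintf("genomotype %s (%dn; %s)\n", x$label, x$ploidy, copies))
  invisible(x)
}

# internal: accept either a genomotype object or a label string
as_genomotype <- function(x) {
  if (inherits(x, "genomotype")) x else genomotype(x)
}
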