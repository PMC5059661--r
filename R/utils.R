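# Shared vocabularies and small sequence helpers.

FEATURE_CLASSES <- c("mRNA", "lncRNA", "miRNA")
SEQ_CLASSES <- c("miRNA", "mRNA_3utr", "lncRNA")
RELATION_TYPES <- c("exp", "a", "b", "inh", "c", "com")
PAIR_CLASSES <- c("lncRNA-mRNA", "miRNA-mRNA", "miRNA-lncRNA")
EDGE_TYPES <- c("mirna_mrna", "mirna_lncrna", "lncrna_mrna")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complement of an RNA sequence
#'
#' @param x character vector of RNA sequences over `{A,C,G,U}`.
#' @return Character vector of per-base complements (not reversed).
#' @keywords internal
rna_complement <- function(x) chartr("ACGU", "UGCA", x)

#' Reverse complement of an RNA sequence
#'
#' @inheritParams rna_complement
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' rna_revcomp("UGAGGUAG")
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(rna_complement(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,U}: %s",
                 what, substr(x[bad][1], 1, 40)), call. = FALSE)
  }
  invisible(TRUE)
}

# Random RNA string(s) of given length from the uniform base distribution.
random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
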