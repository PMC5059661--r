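# Sequence-based miRNA binding-site prediction on mRNA 3'UTRs and lncRNAs:
# a canonical seed-site scanner (8mer / 7mer-m8 / 7mer-A1 / 6mer) plus a
# weighted complementarity alignment score over the site region and its
# 5' flank, used to rank and threshold candidate miRNA-target pairs.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Scan a target sequence for miRNA seed sites
#'
#' Site classes are defined on the target read 5'->3', anchored at each
#' exact Watson-Crick complement of the miRNA seed core (positions 2-7):
#' a 6mer is the core alone; a 7mer-m8 additionally pairs miRNA position
#' 8 (one base 5' on the target); a 7mer-A1 is the core plus a target A
#' across from miRNA position 1 (one base 3' on the target); an 8mer has
#' both. Each core match is reported once, at its best class; overlapping
#' sites at distinct positions are all reported.
#'
#' @param mirna_sequence miRNA sequence over `{A,C,G,U}`, length >= 8,
#'   written 5'->3'.
#' @param target_sequence target sequence over `{A,C,G,U}`, 5'->3'.
#' @return data.frame with columns start, end (0-based, half-open, on the
#'   target, covering the seed-pairing region including the position-1 A
#'   where applicable) and site_type.
#' @export
find_seed_sites <- function(mirna_sequence, target_sequence) {
  check_rna_alphabet(mirna_sequence, "miRNA sequence")
  check_rna_alphabet(target_sequence, "target sequence")
  if (nchar(mirna_sequence) < 8) stop("miRNA sequence must be >= 8 nt")
  core <- rna_revcomp(substr(mirna_sequence, 2, 7))
  m8c <- rna_complement(substr(mirna_sequence, 8, 8))
  tlen <- nchar(target_sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (tlen < 6) return(empty)
  hits <- Biostrings::matchPattern(core,
                                   Biostrings::RNAString(target_sequence))
  pos <- Biostrings::start(hits)  # 1-based core starts, overlapping included
  if (length(pos) == 0) return(empty)
  has_m8 <- pos > 1 &
    substring(target_sequence, pos - 1, pos - 1) == m8c
  has_a1 <- pos + 6 <= tlen &
    substring(target_sequence, pos + 6, pos + 6) == "A"
  site_type <- ifelse(has_m8 & has_a1, "8mer",
                      ifelse(has_m8, "7mer-m8",
                             ifelse(has_a1, "7mer-A1", "6mer")))
  start <- (pos - 1L) - as.integer(has_m8)
  end <- (pos - 1L) + 6L + as.integer(has_a1)
  data.frame(start = start, end = end, site_type = site_type,
             stringsAsFactors = FALSE)
}

# Per-position pairing score between a miRNA base and a target base
# (both read as written, the target window having been reversed so that
# aligned positions are the paired ones): Watson-Crick +5, G:U wobble +2,
# mismatch -3.
pair_score <- function(a, b) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, 5, ifelse(gu, 2, -3))
}

#' Complementarity alignment score of a miRNA against a site window
#'
#' Local alignment (affine gaps) of the miRNA, 5'->3', against the
#' reversed target window, with per-position scores: Watson-Crick match
#' +5, G:U wobble +2, mismatch -3; gap open -8, each gap extension -2.
#' Pairing scores at miRNA seed positions 2-8 count at double weight.
#' The score is floored at 0. A perfect 22-nt complement scores
#' 15*5 + 7*10 = 145 under the defaults.
#'
#' @param mirna_sequence miRNA sequence, 5'->3'.
#' @param target_window the site region extended up to 30 nt on its 5'
#'   side on the target; must be at least 8 nt.
#' @param match,wobble,mismatch,gap_open,gap_extend scoring constants.
#' @return Non-negative alignment score.
#' @export
align_score <- function(mirna_sequence, target_window,
                        match = 5, wobble = 2, mismatch = -3,
                        gap_open = -8, gap_extend = -2) {
  check_rna_alphabet(mirna_sequence, "miRNA sequence")
  check_rna_alphabet(target_window, "target window")
  if (nchar(target_window) < 8)
    stop("target window shorter than the seed region (8 nt)")
  mir <- strsplit(mirna_sequence, "", fixed = TRUE)[[1]]
  win <- rev(strsplit(target_window, "", fixed = TRUE)[[1]])
  n <- length(mir)
  m <- length(win)
  weight <- ifelse(seq_len(n) >= 2 & seq_len(n) <= 8, 2, 1)
  neg <- -Inf
  M <- matrix(0, n + 1, m + 1)  # best score ending in a pairing at (i, j)
  X <- matrix(neg, n + 1, m + 1)  # gap consuming window bases
  Y <- matrix(neg, n + 1, m + 1)  # gap consuming miRNA bases
  M[1, ] <- 0
  M[, 1] <- 0
  best <- 0
  for (i in seq_len(n)) {
    si <- weight[i] * pair_score(rep(mir[i], m), win)
    for (j in seq_len(m)) {
      diag_best <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- diag_best + si[j]
      X[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, X[i + 1, j] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, Y[i, j + 1] + gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  max(0, best)
}

#' Predict candidate miRNA-target pairs from sequence
#'
#' Restricts the scan to differentially expressed miRNAs and targets,
#' finds all seed sites per pair, scores each site's window (the site
#' extended 30 nt 5' on the target) with [align_score()], and reports
#' pairs whose best site scores at least `min_score`.
#'
#' @param mirnas a [sequence_set()] of mature miRNAs.
#' @param targets a [sequence_set()] of mRNA 3'UTRs and/or lncRNAs.
#' @param min_score candidate threshold on the best site score
#'   (default 140: a perfect complement at 145 passes; seed-only matches
#'   do not).
#' @param de_mirnas,de_targets ids to which the scan is restricted; `NULL`
#'   means no restriction.
#' @param flank_5p nt of 5' target context added to each site window.
#' @return data.frame with columns mirna_id, target_id, target_class,
#'   start, end, site_type, align_score (one row per candidate pair,
#'   carrying its best-scoring site).
#' @export
predict_targets <- function(mirnas, targets, min_score = 140,
                            de_mirnas = NULL, de_targets = NULL,
                            flank_5p = 30) {
  stopifnot(inherits(mirnas, "sequence_set"),
            inherits(targets, "sequence_set"))
  if (!is.null(de_mirnas)) mirnas <- mirnas[mirnas$id %in% de_mirnas, ]
  if (!is.null(de_targets)) targets <- targets[targets$id %in% de_targets, ]
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    mir_id <- mirnas$id[i]
    mir_seq <- mirnas$seq[i]
    for (j in seq_len(nrow(targets))) {
      sites <- find_seed_sites(mir_seq, targets$seq[j])
      if (nrow(sites) == 0) next
      tseq <- targets$seq[j]
      scores <- vapply(seq_len(nrow(sites)), function(s) {
        wstart <- max(0L, sites$start[s] - flank_5p)
        align_score(mir_seq, substr(tseq, wstart + 1L, sites$end[s]))
      }, numeric(1))
      best <- which.max(scores)
      if (scores[best] >= min_score) {
        out[[length(out) + 1]] <- data.frame(
          mirna_id = mir_id, target_id = targets$id[j],
          target_class = targets$class[j],
          start = sites$start[best], end = sites$end[best],
          site_type = sites$site_type[best],
          align_score = scores[best],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      align_score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
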