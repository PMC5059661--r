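# Pearson co-expression: profile construction on log2(normalized + 1)
# counts, the high-correlation lncRNA-mRNA pairing rule (|r| >= 0.99 by
# default, positive and negative pairs both retained), and the
# negative-correlation filter that turns sequence-predicted miRNA-target
# candidates into likely true targets.

#' Log-normalized expression profiles
#'
#' Returns `log2(count / size_factor + 1)` per feature and sample; all
#' downstream correlations are computed on these profiles.
#'
#' @param cm a [count_matrix()] (typically restricted to the samples of
#'   one comparison).
#' @param sf size factors; computed from `cm` by default.
#' @return Numeric matrix, features x samples, same dimnames as the
#'   counts.
#' @export
expression_profiles <- function(cm, sf = size_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  log2(sweep(cm$counts, 2, sf, "/") + 1)
}

#' Pearson correlation with degenerate-profile marker
#'
#' The standard product-moment coefficient. Profiles of fewer than 3
#' observations are an error (r on 2 points is always +-1); zero-variance
#' profiles yield `NA`, which downstream pairing excludes.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return r in `[-1, 1]`, or `NA` if either vector has zero variance.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3) stop("profiles must have length >= 3")
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)
}

#' High-correlation lncRNA-mRNA pairs
#'
#' All (lncRNA, mRNA) profile pairs with `|r| >= r_min`; positive and
#' negative pairs are both retained (and counted separately downstream).
#' Zero-variance profiles never pair.
#'
#' @param lncrna_profiles,mrna_profiles numeric matrices (features x
#'   samples, shared sample order) of differentially expressed features,
#'   as from [expression_profiles()].
#' @param r_min threshold on `|r|` (default 0.99).
#' @return data.frame with columns feature_a (lncRNA), feature_b (mRNA),
#'   pair_class, r, sign.
#' @export
lncrna_mrna_pairs <- function(lncrna_profiles, mrna_profiles, r_min = 0.99) {
  empty <- data.frame(feature_a = character(0), feature_b = character(0),
                      pair_class = character(0), r = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE)
  if (nrow(lncrna_profiles) == 0 || nrow(mrna_profiles) == 0) return(empty)
  if (ncol(lncrna_profiles) != ncol(mrna_profiles))
    stop("profile sets must share the sample dimension")
  if (ncol(lncrna_profiles) < 3)
    stop("profiles must span >= 3 samples")
  suppressWarnings(
    R <- cor(t(lncrna_profiles), t(mrna_profiles)))  # lncRNA x mRNA
  R[is.na(R)] <- 0  # zero-variance profiles: never pass |r| >= r_min > 0
  hit <- which(abs(R) >= r_min, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  r <- R[hit]
  data.frame(
    feature_a = rownames(lncrna_profiles)[hit[, 1]],
    feature_b = rownames(mrna_profiles)[hit[, 2]],
    pair_class = "lncRNA-mRNA",
    r = r,
    sign = ifelse(r > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
}

#' Negative-correlation filter for predicted miRNA targets
#'
#' A sequence-predicted candidate is kept as a likely true target only
#' when the miRNA and the target are negatively correlated
#' (`r < r_max_neg`, strictly negative by default). Applied identically
#' to miRNA-mRNA and miRNA-lncRNA candidates.
#'
#' @param candidates data.frame from [predict_targets()].
#' @param mirna_profiles,target_profiles numeric matrices (features x
#'   samples, shared sample order) containing every candidate member.
#' @param r_max_neg retain pairs with `r` strictly below this (default 0).
#' @return The retained candidates with columns feature_a (miRNA),
#'   feature_b (target), pair_class, r, sign, plus the site columns.
#' @export
negative_filter <- function(candidates, mirna_profiles, target_profiles,
                            r_max_neg = 0) {
  empty <- data.frame(feature_a = character(0), feature_b = character(0),
                      pair_class = character(0), r = numeric(0),
                      sign = character(0), target_class = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), align_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  miss_m <- setdiff(unique(candidates$mirna_id), rownames(mirna_profiles))
  if (length(miss_m) > 0)
    stop(sprintf("no expression profile for miRNA: %s", miss_m[1]))
  miss_t <- setdiff(unique(candidates$target_id), rownames(target_profiles))
  if (length(miss_t) > 0)
    stop(sprintf("no expression profile for target: %s", miss_t[1]))
  r <- vapply(seq_len(nrow(candidates)), function(i) {
    pearson(mirna_profiles[candidates$mirna_id[i], ],
            target_profiles[candidates$target_id[i], ])
  }, numeric(1))
  keep <- !is.na(r) & r < r_max_neg
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  data.frame(
    feature_a = out$mirna_id,
    feature_b = out$target_id,
    pair_class = ifelse(out$target_class == "lncRNA",
                        "miRNA-lncRNA", "miRNA-mRNA"),
    r = r[keep],
    sign = "negative",
    target_class = out$target_class,
    start = out$start, end = out$end, site_type = out$site_type,
    align_score = out$align_score,
    stringsAsFactors = FALSE)
}

#' Write a pair table as TSV
#'
#' @param pairs data.frame from [lncrna_mrna_pairs()] or
#'   [negative_filter()].
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
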