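# Two-group differential expression for RNA-seq counts:
# median-of-ratios size factors, per-feature method-of-moments dispersion,
# and the exact two-sided negative-binomial test that conditions on the
# observed count total, followed by class-specific calling rules
# (fold-change + FDR for mRNA/lncRNA, |log2FC| + raw P for miRNA).

#' Median-of-ratios size factors
#'
#' For sample j, the size factor is the median over features f (restricted
#' to features with strictly positive geometric mean across samples) of
#' `count[f, j] / geomean(count[f, ])`.
#'
#' @param x a [count_matrix()] or a numeric count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("normalization infeasible: no feature has nonzero counts in every sample")
  geo <- exp(loggeo[use])
  sf <- apply(m[use, , drop = FALSE], 2, function(col) median(col / geo))
  if (any(!is.finite(sf) | sf <= 0))
    stop("normalization infeasible: non-positive size factor")
  sf
}

#' Exact two-sided NB test for one count split
#'
#' Conditions on the total `ka + kb`: the p-value is the summed
#' probability of all splits `(a, b)` of the total whose probability under
#' `NB(mu_a, size_a) x NB(mu_b, size_b)` is at most that of the observed
#' split (within a relative tolerance of 1e-7), divided by the total
#' probability of the split sum. Computed in log space for stability.
#'
#' @param ka,kb observed group count totals.
#' @param mu_a,mu_b,size_a,size_b negative-binomial parameters of the two
#'   group totals (mean / size parameterization).
#' @return The two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(ka, kb, mu_a, size_a, mu_b, size_b) {
  ks <- ka + kb
  if (ks == 0) return(1)
  i <- 0:ks
  l <- dnbinom(i, mu = mu_a, size = size_a, log = TRUE) +
    dnbinom(ks - i, mu = mu_b, size = size_b, log = TRUE)
  lobs <- l[ka + 1]
  m <- max(l)
  num <- sum(exp(l[l <= lobs + 1e-7] - m))
  den <- sum(exp(l - m))
  min(1, num / den)
}

#' Exact NB differential-expression test between two groups
#'
#' Counts are normalized internally with [size_factors()] computed on the
#' samples of the two groups. Per-feature dispersion is estimated by
#' method of moments on the normalized counts pooled across both groups
#' (pooled within-group variance v; `alpha = (v - q) / q^2`), floored at
#' `dispersion_floor`. The test conditions on the rounded total of
#' normalized counts: the group totals are modelled as sums of n
#' independent NB(q, alpha) variables, i.e. `NB(n q, n / alpha)`, and
#' compared with [nb_exact_test()]. Working on normalized totals makes
#' the p-values exactly invariant to rescaling any sample's column
#' together with its size factor. Fold changes use a pseudocount of 0.5
#' on both normalized group means.
#'
#' @param cm a [count_matrix()].
#' @param group_a test group label; `fold_change = mean_a / mean_b`.
#' @param group_b reference group label.
#' @param allow_no_replicates with a single sample in a group, dispersion
#'   cannot be estimated per feature; if `TRUE` a single "blind" dispersion
#'   (the median of per-feature moments estimates treating all samples as
#'   replicates) is shared across features, with a warning.
#' @param dispersion_floor lower bound on the NB dispersion alpha
#'   (variance = mu + alpha mu^2).
#' @param sf optional size-factor override (named or positional for the
#'   samples of the two groups, group_a samples first); defaults to
#'   median-of-ratios estimation on those samples.
#' @return data.frame with one row per feature: feature_id, class,
#'   base_mean, mean_a, mean_b, fold_change, log2fc, p_value.
#' @export
nb_test <- function(cm, group_a, group_b, allow_no_replicates = FALSE,
                    dispersion_floor = 1e-8, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (group_a == group_b) stop("group_a and group_b must differ")
  idx_a <- which(cm$sample_group == group_a)
  idx_b <- which(cm$sample_group == group_b)
  if (length(idx_a) == 0) stop(sprintf("no samples in group '%s'", group_a))
  if (length(idx_b) == 0) stop(sprintf("no samples in group '%s'", group_b))
  if (min(length(idx_a), length(idx_b)) < 2 && !allow_no_replicates)
    stop("a group has a single sample; set allow_no_replicates = TRUE to use a shared blind dispersion")
  raw <- cm$counts[, c(idx_a, idx_b), drop = FALSE]
  if (is.null(sf)) {
    sf <- size_factors(raw)
  } else {
    if (length(sf) != ncol(raw) || any(sf <= 0))
      stop("sf must hold one positive factor per sample of the two groups")
    if (!is.null(names(sf))) sf <- sf[colnames(raw)]
  }
  norm <- sweep(raw, 2, sf, "/")
  na <- length(idx_a)
  nb <- length(idx_b)
  A <- norm[, seq_len(na), drop = FALSE]
  B <- norm[, na + seq_len(nb), drop = FALSE]
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  q <- rowMeans(norm)
  if (na >= 2 && nb >= 2) {
    v <- ((na - 1) * rowVars(A) + (nb - 1) * rowVars(B)) / (na + nb - 2)
    alpha <- (v - q) / q^2
  } else {
    warning("no replicates in a group: using a single blind dispersion pooled across features")
    v <- rowVars(norm)
    a_f <- (v - q) / q^2
    a_f <- a_f[is.finite(a_f)]
    alpha <- rep(if (length(a_f) > 0) median(a_f) else dispersion_floor,
                 nrow(norm))
  }
  alpha[!is.finite(alpha)] <- dispersion_floor
  alpha <- pmax(alpha, dispersion_floor)
  ka <- as.integer(round(rowSums(A)))
  kb <- as.integer(round(rowSums(B)))
  p <- vapply(seq_len(nrow(raw)), function(f) {
    if (q[f] == 0) return(1)
    nb_exact_test(ka[f], kb[f],
                  mu_a = q[f] * na, size_a = na / alpha[f],
                  mu_b = q[f] * nb, size_b = nb / alpha[f])
  }, numeric(1))
  fold_change <- (mean_a + 0.5) / (mean_b + 0.5)
  data.frame(
    feature_id = rownames(raw),
    class = unname(cm$feature_class[rownames(raw)]),
    base_mean = unname(q),
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    fold_change = unname(fold_change),
    log2fc = unname(log2(fold_change)),
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q_(i) = min_(j>=i) p_(j) m / j`, capped at 1 and
#' returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential-expression calling thresholds
#'
#' mRNAs and lncRNAs are called with fold-change bounds plus an FDR cap;
#' miRNAs with a |log2 fold change| bound plus a raw-P cap. All
#' inequalities are strict, so values exactly at a threshold are `ns`.
#'
#' @param fc_up fold-change ratio above which an mRNA/lncRNA can be
#'   called up (default 1.5).
#' @param fc_down ratio below which it can be called down (default 0.667).
#' @param fdr_max adjusted-p cap for mRNA/lncRNA calls (default 0.05).
#' @param mirna_abs_log2fc |log2FC| bound for miRNA calls (default 1).
#' @param mirna_p_max raw-p cap for miRNA calls (default 0.05).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_up = 1.5, fc_down = 0.667, fdr_max = 0.05,
                          mirna_abs_log2fc = 1, mirna_p_max = 0.05) {
  if (!(fc_up > 1)) stop_field("fc_up", "must be > 1")
  if (!(fc_down > 0 && fc_down < 1)) stop_field("fc_down", "must be in (0, 1)")
  if (!(fdr_max > 0 && fdr_max <= 1)) stop_field("fdr_max", "must be in (0, 1]")
  if (!(mirna_abs_log2fc > 0)) stop_field("mirna_abs_log2fc", "must be > 0")
  if (!(mirna_p_max > 0 && mirna_p_max <= 1))
    stop_field("mirna_p_max", "must be in (0, 1]")
  structure(list(fc_up = fc_up, fc_down = fc_down, fdr_max = fdr_max,
                 mirna_abs_log2fc = mirna_abs_log2fc,
                 mirna_p_max = mirna_p_max),
            class = "de_thresholds")
}

#' Apply calling thresholds to differential-expression results
#'
#' Adds BH-adjusted p-values (`fdr`) when absent and a `call` column:
#' for mRNA/lncRNA, up iff `fold_change > fc_up` and `fdr < fdr_max`, down
#' iff `fold_change < fc_down` and `fdr < fdr_max`; for miRNA, up iff
#' `log2fc > mirna_abs_log2fc` and `p_value < mirna_p_max`, down
#' symmetrically; otherwise `ns`.
#'
#' @param results data.frame from [nb_test()].
#' @param thresholds a [de_thresholds()].
#' @param feature_class class whose rule to apply; defaults to the class
#'   column of `results` (must then be uniform).
#' @return `results` with `fdr` and `call` columns.
#' @export
call_de <- function(results, thresholds = de_thresholds(),
                    feature_class = NULL) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (is.null(feature_class)) {
    feature_class <- unique(results$class)
    if (length(feature_class) != 1)
      stop("results mix feature classes; pass feature_class explicitly")
  }
  if (!feature_class %in% FEATURE_CLASSES)
    stop(sprintf("unknown feature_class: %s", feature_class))
  if (!"fdr" %in% colnames(results))
    results$fdr <- bh_adjust(results$p_value)
  if (feature_class == "miRNA") {
    up <- results$log2fc > thresholds$mirna_abs_log2fc &
      results$p_value < thresholds$mirna_p_max
    down <- results$log2fc < -thresholds$mirna_abs_log2fc &
      results$p_value < thresholds$mirna_p_max
  } else {
    up <- results$fold_change > thresholds$fc_up &
      results$fdr < thresholds$fdr_max
    down <- results$fold_change < thresholds$fc_down &
      results$fdr < thresholds$fdr_max
  }
  results$call <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

#' Write a differential-expression table as TSV
#'
#' @param results a called DE data.frame from [call_de()].
#' @param path output path.
#' @export
write_de_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
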