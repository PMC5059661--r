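# Synthetic cohorts with planted regulatory structure. The generator
# emulates the three-breed ovarian design the pipeline targets (two
# high-fecundity Han genotypes plus a Dorset control), with negative
# binomial counts, planted group effects, miRNA-mediated repression that
# induces anticorrelation between miRNAs and their targets, lncRNA-mRNA
# co-expression through a shared per-sample latent factor, and planted
# miRNA complementary sites embedded in target sequences. Ground truth
# (effects, edges, site positions) is returned for evaluation.

#' Simulation configuration
#'
#' Defaults describe the reference cohort: 500 mRNAs, 50 lncRNAs and 20
#' miRNAs over three breed groups with five replicates each, NB dispersion
#' 0.05 (variance = mu + alpha mu^2), 10% planted DE at 4-fold effect,
#' repression factor 0.25 per standardized unit of miRNA log elevation,
#' and per-sample library size factors log-uniform in `[0.5, 2]`.
#'
#' @param n_mrna,n_lncrna,n_mirna feature counts per class.
#' @param groups ordered group labels (default emulates HanBB / Han++ /
#'   Dorset).
#' @param n_per_group replicates per group; at least 3 so Pearson
#'   correlations over samples are meaningful.
#' @param base_mean_log_range range of log2 baseline means, drawn
#'   uniformly (default `c(3, 8)`, i.e. means 8-256).
#' @param dispersion NB dispersion alpha; 0 gives the Poisson limit.
#' @param frac_de fraction of features with a planted group effect.
#' @param fc_magnitude planted fold change (> 1); direction is random.
#' @param n_mirna_mrna_edges,n_mirna_lncrna_edges,n_lncrna_mrna_edges
#'   planted edge counts for the three pair classes.
#' @param repression_factor multiplicative down-scaling of a target's
#'   group mean per unit of the regulator miRNA's standardized log group
#'   mean; in (0, 1], 1 = no repression.
#' @param utr_length,lncrna_length simulated sequence lengths (nt).
#' @param latent_sd standard deviation (log2 scale) of the shared
#'   per-sample latent factor driving planted lncRNA-mRNA co-expression.
#' @param size_factor_range per-sample library size factors are drawn
#'   log-uniformly from this range.
#' @param ann_n_terms,ann_frac_de,ann_background annotation simulation:
#'   number of terms, fraction of planted-DE mRNAs in the enriched term,
#'   and number of background genes added to it.
#' @param rng_seed integer seed; the full cohort is reproducible from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_mrna = 500, n_lncrna = 50, n_mirna = 20,
                              groups = c("HanBB", "HanPP", "Dorset"),
                              n_per_group = 5,
                              base_mean_log_range = c(3, 8),
                              dispersion = 0.05,
                              frac_de = 0.1, fc_magnitude = 4,
                              n_mirna_mrna_edges = 30,
                              n_mirna_lncrna_edges = 10,
                              n_lncrna_mrna_edges = 10,
                              repression_factor = 0.25,
                              utr_length = 500, lncrna_length = 800,
                              latent_sd = 2,
                              size_factor_range = c(0.5, 2),
                              ann_n_terms = 10, ann_frac_de = 0.8,
                              ann_background = 10,
                              rng_seed = 1) {
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              groups = as.character(groups), n_per_group = n_per_group,
              base_mean_log_range = base_mean_log_range,
              dispersion = dispersion, frac_de = frac_de,
              fc_magnitude = fc_magnitude,
              n_mirna_mrna_edges = n_mirna_mrna_edges,
              n_mirna_lncrna_edges = n_mirna_lncrna_edges,
              n_lncrna_mrna_edges = n_lncrna_mrna_edges,
              repression_factor = repression_factor,
              utr_length = utr_length, lncrna_length = lncrna_length,
              latent_sd = latent_sd,
              size_factor_range = size_factor_range,
              ann_n_terms = ann_n_terms, ann_frac_de = ann_frac_de,
              ann_background = ann_background,
              rng_seed = rng_seed)
  for (f in c("n_mrna", "n_lncrna", "n_mirna"))
    if (cfg[[f]] < 1) stop_field(f, "must be >= 1")
  if (length(cfg$groups) < 2 || anyDuplicated(cfg$groups))
    stop_field("groups", "must be >= 2 distinct labels")
  if (cfg$n_per_group < 3) stop_field("n_per_group", "must be >= 3")
  if (length(cfg$base_mean_log_range) != 2 ||
      diff(cfg$base_mean_log_range) < 0)
    stop_field("base_mean_log_range", "must be an increasing range")
  if (cfg$dispersion < 0) stop_field("dispersion", "must be >= 0")
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    stop_field("frac_de", "must be in [0, 1]")
  if (cfg$fc_magnitude <= 1) stop_field("fc_magnitude", "must be > 1")
  if (cfg$repression_factor <= 0 || cfg$repression_factor > 1)
    stop_field("repression_factor", "must be in (0, 1]")
  for (f in c("n_mirna_mrna_edges", "n_mirna_lncrna_edges",
              "n_lncrna_mrna_edges"))
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  if (cfg$utr_length < 44) stop_field("utr_length", "must be >= 44")
  if (cfg$lncrna_length < 44) stop_field("lncrna_length", "must be >= 44")
  if (cfg$latent_sd < 0) stop_field("latent_sd", "must be >= 0")
  if (length(cfg$size_factor_range) != 2 || any(cfg$size_factor_range <= 0))
    stop_field("size_factor_range", "must be two positive values")
  if (cfg$ann_n_terms < 1) stop_field("ann_n_terms", "must be >= 1")
  if (cfg$ann_frac_de < 0 || cfg$ann_frac_de > 1)
    stop_field("ann_frac_de", "must be in [0, 1]")
  if (cfg$ann_background < 0) stop_field("ann_background", "must be >= 0")
  if (cfg$rng_seed != round(cfg$rng_seed))
    stop_field("rng_seed", "must be an integer")
  # feasibility of disjoint planted roles among mRNAs / lncRNAs
  n_de_mrna <- round(cfg$frac_de * cfg$n_mrna)
  if (n_de_mrna + cfg$n_mirna_mrna_edges + cfg$n_lncrna_mrna_edges >
      cfg$n_mrna)
    stop_field("n_mirna_mrna_edges",
               "too many planted mRNA roles for n_mrna")
  n_de_lnc <- round(cfg$frac_de * cfg$n_lncrna)
  if (max(n_de_lnc, cfg$n_lncrna_mrna_edges) + cfg$n_mirna_lncrna_edges >
      cfg$n_lncrna)
    stop_field("n_mirna_lncrna_edges",
               "too many planted lncRNA roles for n_lncrna")
  structure(cfg, class = "simulation_config")
}

# sample() without the length-1 surprise
sample_vec <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

draw_counts <- function(mu, alpha) {
  k <- if (alpha == 0) rpois(length(mu), lambda = mu)
  else rnbinom(length(mu), mu = mu, size = 1 / alpha)
  matrix(k, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate cohort count matrices with planted structure
#'
#' Counts are NB(mu, alpha) with
#' `mu[f, s] = baseline_f x effect[f, group(s)] x latent[f, s] x sf_s`.
#' Planted group effects multiply one group's mean by the fold change;
#' for each planted miRNA->target edge the target's group mean is scaled
#' by `repression_factor^z_g`, where `z_g` is the regulator miRNA's
#' standardized log group mean, which induces negative expression
#' correlation across groups. Planted lncRNA-mRNA pairs share a
#' per-sample latent factor (same loading for positive pairs, opposite
#' for negative ones), producing near-collinear profiles. Regulator
#' miRNAs and co-expressed lncRNAs are drawn from (and, if needed,
#' promoted into) the planted-DE sets, since only differentially
#' expressed features enter the downstream networks.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (named list of [count_matrix()] per class)
#'   and `truth` (class `ground_truth`: per-class group-effect matrices,
#'   DE feature sets, planted edge tables, sample size factors).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  groups <- config$groups
  ng <- length(groups)
  nsamp <- ng * config$n_per_group
  sample_ids <- paste0(rep(groups, each = config$n_per_group), "_",
                       rep(seq_len(config$n_per_group), times = ng))
  sample_group <- setNames(rep(groups, each = config$n_per_group),
                           sample_ids)
  sf <- exp(runif(nsamp, log(config$size_factor_range[1]),
                  log(config$size_factor_range[2])))
  names(sf) <- sample_ids

  ids <- list(
    mRNA = sprintf("gene_%04d", seq_len(config$n_mrna)),
    lncRNA = sprintf("lnc_%03d", seq_len(config$n_lncrna)),
    miRNA = sprintf("mir_%02d", seq_len(config$n_mirna)))
  n_feat <- c(mRNA = config$n_mrna, lncRNA = config$n_lncrna,
              miRNA = config$n_mirna)

  baseline <- list()
  effect <- list()
  de_idx <- list()
  for (cls in names(ids)) {
    n <- n_feat[[cls]]
    baseline[[cls]] <- setNames(
      2^runif(n, config$base_mean_log_range[1],
              config$base_mean_log_range[2]), ids[[cls]])
    E <- matrix(1, n, ng, dimnames = list(ids[[cls]], groups))
    idx <- sample_vec(seq_len(n), round(config$frac_de * n))
    for (i in idx) {
      g <- sample.int(ng, 1)
      E[i, g] <- config$fc_magnitude^sample(c(1, -1), 1)
    }
    effect[[cls]] <- E
    de_idx[[cls]] <- idx
  }

  plant_effect <- function(E, i, fc) {
    g <- sample.int(ncol(E), 1)
    E[i, g] <- fc^sample(c(1, -1), 1)
    E
  }

  # regulator miRNAs: drawn from the DE set, promoted if the set is small
  n_edges_mi <- config$n_mirna_mrna_edges + config$n_mirna_lncrna_edges
  pool_size <- min(config$n_mirna, max(3, ceiling(n_edges_mi / 5)))
  pool <- de_idx$miRNA
  if (n_edges_mi > 0 && length(pool) < pool_size) {
    extra <- sample_vec(setdiff(seq_len(config$n_mirna), pool),
                        pool_size - length(pool))
    for (i in extra)
      effect$miRNA <- plant_effect(effect$miRNA, i, config$fc_magnitude)
    pool <- c(pool, extra)
  }

  apply_repression <- function(E_target, tgt, mir_row) {
    zlog <- log(mir_row)
    z <- (zlog - mean(zlog)) / sd(zlog)
    E_target[tgt, ] <- E_target[tgt, ] * config$repression_factor^z
    E_target
  }

  free_mrna <- setdiff(seq_len(config$n_mrna), de_idx$mRNA)
  free_lnc <- setdiff(seq_len(config$n_lncrna), de_idx$lncRNA)

  mm_edges <- data.frame(mirna_id = character(0), target_id = character(0),
                         stringsAsFactors = FALSE)
  if (config$n_mirna_mrna_edges > 0) {
    tgt <- sample_vec(free_mrna, config$n_mirna_mrna_edges)
    free_mrna <- setdiff(free_mrna, tgt)
    reg <- sample_vec(pool, config$n_mirna_mrna_edges, replace = TRUE)
    for (e in seq_along(tgt))
      effect$mRNA <- apply_repression(effect$mRNA, tgt[e],
                                      effect$miRNA[reg[e], ])
    mm_edges <- data.frame(mirna_id = ids$miRNA[reg],
                           target_id = ids$mRNA[tgt],
                           stringsAsFactors = FALSE)
  }

  ml_edges <- data.frame(mirna_id = character(0), target_id = character(0),
                         stringsAsFactors = FALSE)
  if (config$n_mirna_lncrna_edges > 0) {
    tgt <- sample_vec(free_lnc, config$n_mirna_lncrna_edges)
    free_lnc <- setdiff(free_lnc, tgt)
    reg <- sample_vec(pool, config$n_mirna_lncrna_edges, replace = TRUE)
    for (e in seq_along(tgt))
      effect$lncRNA <- apply_repression(effect$lncRNA, tgt[e],
                                        effect$miRNA[reg[e], ])
    ml_edges <- data.frame(mirna_id = ids$miRNA[reg],
                           target_id = ids$lncRNA[tgt],
                           stringsAsFactors = FALSE)
  }

  lm_edges <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                         sign = character(0), stringsAsFactors = FALSE)
  latent <- list(
    mRNA = matrix(0, config$n_mrna, nsamp,
                  dimnames = list(ids$mRNA, sample_ids)),
    lncRNA = matrix(0, config$n_lncrna, nsamp,
                    dimnames = list(ids$lncRNA, sample_ids)),
    miRNA = matrix(0, config$n_mirna, nsamp,
                   dimnames = list(ids$miRNA, sample_ids)))
  if (config$n_lncrna_mrna_edges > 0) {
    lnc_pool <- intersect(de_idx$lncRNA, free_lnc)
    if (length(lnc_pool) < config$n_lncrna_mrna_edges) {
      extra <- sample_vec(setdiff(free_lnc, lnc_pool),
                          config$n_lncrna_mrna_edges - length(lnc_pool))
      for (i in extra)
        effect$lncRNA <- plant_effect(effect$lncRNA, i, config$fc_magnitude)
      lnc_pool <- c(lnc_pool, extra)
    }
    lnc <- sample_vec(lnc_pool, config$n_lncrna_mrna_edges)
    par <- sample_vec(free_mrna, config$n_lncrna_mrna_edges)
    sgn <- rep(c(1, -1), length.out = config$n_lncrna_mrna_edges)
    for (e in seq_along(lnc)) {
      effect$mRNA[par[e], ] <- effect$lncRNA[lnc[e], ]^sgn[e]
      lam <- rnorm(nsamp, 0, config$latent_sd)
      latent$lncRNA[lnc[e], ] <- latent$lncRNA[lnc[e], ] + lam
      latent$mRNA[par[e], ] <- latent$mRNA[par[e], ] + sgn[e] * lam
    }
    lm_edges <- data.frame(lncrna_id = ids$lncRNA[lnc],
                           mrna_id = ids$mRNA[par],
                           sign = ifelse(sgn > 0, "positive", "negative"),
                           stringsAsFactors = FALSE)
  }

  grp_idx <- match(sample_group, groups)
  counts <- list()
  for (cls in names(ids)) {
    mu <- baseline[[cls]] * effect[[cls]][, grp_idx, drop = FALSE] *
      2^latent[[cls]]
    mu <- sweep(mu, 2, sf, "*")
    colnames(mu) <- sample_ids
    counts[[cls]] <- count_matrix(draw_counts(mu, config$dispersion),
                                  cls, sample_group)
  }

  de_features <- lapply(effect, function(E) {
    rownames(E)[apply(abs(log(E)) > 1e-9, 1, any)]
  })

  truth <- structure(list(
    group_effect = effect,
    baseline = baseline,
    de_features = de_features,
    edges = list(mirna_mrna = mm_edges, mirna_lncrna = ml_edges,
                 lncrna_mrna = lm_edges),
    sites = NULL,
    size_factors = sf,
    config = config
  ), class = "ground_truth")

  list(counts = counts, truth = truth)
}

#' Features with a true effect between two groups
#'
#' @param truth a `ground_truth` from [simulate_counts()].
#' @param class feature class.
#' @param group_a,group_b the contrasted groups.
#' @return Character vector of feature ids whose true group means differ
#'   between the two groups.
#' @export
true_de_features <- function(truth, class, group_a, group_b) {
  E <- truth$group_effect[[class]]
  rownames(E)[abs(log(E[, group_a] / E[, group_b])) > 1e-9]
}

# All occurrences (overlapping) of any miRNA seed core in a sequence,
# as 1-based start positions per core.
core_hits <- function(seq, cores) {
  hits <- lapply(cores, function(core) {
    Biostrings::start(Biostrings::matchPattern(
      core, Biostrings::RNAString(seq)))
  })
  hits
}

#' Simulate cohort sequences with embedded miRNA sites
#'
#' miRNA mature sequences are random 22-mers with a 5' U (so the planted
#' site carries an A across from miRNA position 1, as in canonical 8mer
#' sites). For every planted miRNA->target edge the target sequence
#' contains, at a recorded position, the full reverse complement of the
#' miRNA; its seed-pairing region is the exact reverse complement of
#' miRNA positions 2-8 followed by that A, i.e. an 8mer site. Outside
#' planted site regions, all sequences are rejection-sampled so that no
#' 6mer-or-better seed match exists for any simulated miRNA.
#'
#' @param config the [simulation_config()] used for the counts.
#' @param truth the matching `ground_truth` from [simulate_counts()].
#' @param max_passes cap on rejection-resampling sweeps per sequence.
#' @return list with `sequences` (a [sequence_set()] of miRNAs, mRNA
#'   3'UTRs and lncRNAs) and `truth` (input truth with a `sites` table:
#'   mirna_id, target_id, target_class, start, end, site_type; 0-based
#'   half-open).
#' @export
simulate_sequences <- function(config, truth, max_passes = 100) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  set.seed(config$rng_seed + 1L)
  mir_ids <- rownames(truth$group_effect$miRNA)
  mir_seq <- setNames(paste0("U", random_rna(length(mir_ids), 21)), mir_ids)
  cores <- setNames(rna_revcomp(substr(mir_seq, 2, 7)), mir_ids)

  with_class <- function(e, cls) {
    if (nrow(e) == 0) {
      return(data.frame(mirna_id = character(0), target_id = character(0),
                        target_class = character(0),
                        stringsAsFactors = FALSE))
    }
    cbind(e, target_class = cls, stringsAsFactors = FALSE)
  }
  edges <- rbind(with_class(truth$edges$mirna_mrna, "mRNA_3utr"),
                 with_class(truth$edges$mirna_lncrna, "lncRNA"))
  site_of <- setNames(edges$mirna_id, edges$target_id)

  clean_sequence <- function(seq, allowed_lo, allowed_hi) {
    # resample positions of seed-core hits outside [allowed_lo, allowed_hi]
    len <- nchar(seq)
    for (pass in seq_len(max_passes)) {
      hits <- core_hits(seq, cores)
      bad_pos <- integer(0)
      for (h in hits) {
        for (p in h) {
          span <- p:(p + 5)
          outside <- span[span < allowed_lo | span > allowed_hi]
          bad_pos <- c(bad_pos, outside)
        }
      }
      bad_pos <- unique(bad_pos)
      if (length(bad_pos) == 0) return(seq)
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      chars[bad_pos] <- sample(c("A", "C", "G", "U"), length(bad_pos),
                               replace = TRUE)
      seq <- paste(chars, collapse = "")
    }
    stop("rejection sampling exceeded the retry cap; use longer sequences or fewer miRNAs")
  }

  build_targets <- function(feat_ids, len, class) {
    seqs <- character(length(feat_ids))
    sites <- list()
    for (i in seq_along(feat_ids)) {
      fid <- feat_ids[i]
      seq <- random_rna(1, len)
      lo <- 0L; hi <- -1L  # empty allowed region
      if (fid %in% names(site_of)) {
        mir <- site_of[[fid]]
        site <- rna_revcomp(mir_seq[[mir]])  # 22 nt, ends ...A
        pos0 <- sample.int(len - 22L + 1L, 1) - 1L  # 0-based embed start
        substr(seq, pos0 + 1L, pos0 + 22L) <- site
        lo <- pos0 + 1L; hi <- pos0 + 22L
        sites[[length(sites) + 1]] <- data.frame(
          mirna_id = mir, target_id = fid, target_class = class,
          start = pos0 + 14L, end = pos0 + 22L, site_type = "8mer",
          stringsAsFactors = FALSE)
      }
      seq <- clean_sequence(seq, lo, hi)
      if (fid %in% names(site_of)) {
        mir <- site_of[[fid]]
        substr(seq, lo, hi) <- rna_revcomp(mir_seq[[mir]])
      }
      seqs[i] <- seq
    }
    list(seqs = setNames(seqs, feat_ids),
         sites = if (length(sites)) do.call(rbind, sites) else NULL)
  }

  utr <- build_targets(rownames(truth$group_effect$mRNA),
                       config$utr_length, "mRNA_3utr")
  lnc <- build_targets(rownames(truth$group_effect$lncRNA),
                       config$lncrna_length, "lncRNA")

  sequences <- sequence_set(
    id = c(mir_ids, names(utr$seqs), names(lnc$seqs)),
    seq = c(unname(mir_seq), unname(utr$seqs), unname(lnc$seqs)),
    class = c(rep("miRNA", length(mir_ids)),
              rep("mRNA_3utr", length(utr$seqs)),
              rep("lncRNA", length(lnc$seqs))))
  sites <- rbind(utr$sites, lnc$sites)
  if (is.null(sites))
    sites <- data.frame(mirna_id = character(0), target_id = character(0),
                        target_class = character(0), start = integer(0),
                        end = integer(0), site_type = character(0),
                        stringsAsFactors = FALSE)
  truth$sites <- sites
  list(sequences = sequences, truth = truth)
}

#' Simulate a gene-to-term annotation with one planted enriched term
#'
#' The planted term contains a fraction (`ann_frac_de`) of the planted-DE
#' mRNAs plus `ann_background` background genes; the remaining terms are
#' random gene sets of the same size.
#'
#' @param config a [simulation_config()].
#' @param truth the matching `ground_truth`.
#' @param seed RNG seed for the annotation draw (defaults to
#'   `rng_seed + 2`).
#' @return An [annotation_map()]; the planted term's id is in
#'   `attr(, "planted_term")`.
#' @export
simulate_annotation <- function(config, truth, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  set.seed(seed %||% (config$rng_seed + 2L))
  universe <- rownames(truth$group_effect$mRNA)
  de <- truth$de_features$mRNA
  if (length(de) == 0)
    stop("no planted DE mRNAs to build an enriched term from")
  k_de <- max(1L, round(config$ann_frac_de * length(de)))
  bg <- setdiff(universe, de)
  enriched <- c(sample_vec(de, k_de),
                sample_vec(bg, min(config$ann_background, length(bg))))
  size <- length(enriched)
  terms <- list(term_01 = enriched)
  if (config$ann_n_terms > 1) {
    for (t in 2:config$ann_n_terms)
      terms[[sprintf("term_%02d", t)]] <- sample_vec(universe, size)
  }
  nm <- setNames(c("planted enriched term",
                   rep("random term", config$ann_n_terms - 1)),
                 names(terms))
  out <- annotation_map(terms, nm)
  attr(out, "planted_term") <- "term_01"
  out
}

#' Simulate a full cohort: counts, sequences, annotation, ground truth
#'
#' Convenience wrapper running [simulate_counts()],
#' [simulate_sequences()] and [simulate_annotation()] with one config.
#'
#' @param config a [simulation_config()].
#' @return list with `counts`, `sequences`, `annotation`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  cc <- simulate_counts(config)
  sq <- simulate_sequences(config, cc$truth)
  ann <- simulate_annotation(config, sq$truth)
  list(counts = cc$counts, sequences = sq$sequences, annotation = ann,
       truth = sq$truth, config = config)
}
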