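# End-to-end orchestration: simulate (or load) a cohort, then per
# comparison run differential expression, target prediction, correlation
# pairing, network assembly and enrichment; write every artifact with a
# checksum manifest, and in simulation mode evaluate against the planted
# ground truth.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param simulation a [simulation_config()] for simulation mode, or
#'   `NULL` when `input` is given.
#' @param input for user data: a list with elements `counts` (named list
#'   of [count_matrix()] per class: mRNA, lncRNA, miRNA), `sequences` (a
#'   [sequence_set()] covering miRNAs and targets), and optionally
#'   `annotation` (an [annotation_map()]) and `relations` (a
#'   [read_relations()] table).
#' @param comparisons list of `c(test_group, reference_group)` pairs;
#'   the default mirrors a three-breed design (each Han genotype against
#'   the Dorset control plus the Han-Han contrast).
#' @param thresholds a [de_thresholds()].
#' @param min_score candidate threshold for [predict_targets()].
#' @param r_min lncRNA-mRNA |r| threshold (default 0.99).
#' @param r_max_neg miRNA-target correlation cap (default 0: strictly
#'   negative).
#' @param enrich_p raw-p threshold for the enriched flag.
#' @param hub_quantile degree quantile defining hubs.
#' @param allow_no_replicates passed to [nb_test()].
#' @param seed integer seed for any pipeline-level randomness.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = simulation_config(),
                            input = NULL,
                            comparisons = list(c("HanBB", "Dorset"),
                                               c("HanPP", "Dorset"),
                                               c("HanBB", "HanPP")),
                            thresholds = de_thresholds(),
                            min_score = 140, r_min = 0.99, r_max_neg = 0,
                            enrich_p = 0.05, hub_quantile = 0.9,
                            allow_no_replicates = FALSE, seed = 1) {
  if (is.null(simulation) && is.null(input))
    stop("either a simulation config or input data must be given")
  for (cmp in comparisons) {
    if (length(cmp) != 2 || cmp[1] == cmp[2])
      stop("each comparison must name two distinct groups")
  }
  stopifnot(inherits(thresholds, "de_thresholds"))
  structure(list(out_dir = out_dir, simulation = simulation, input = input,
                 comparisons = comparisons, thresholds = thresholds,
                 min_score = min_score, r_min = r_min,
                 r_max_neg = r_max_neg, enrich_p = enrich_p,
                 hub_quantile = hub_quantile,
                 allow_no_replicates = allow_no_replicates, seed = seed),
            class = "pipeline_config")
}

comparison_label <- function(cmp) paste0(cmp[1], "_vs_", cmp[2])

#' Run one comparison of the integrative analysis
#'
#' Differential expression per class, sequence target prediction for the
#' DE miRNAs restricted to DE targets, negative-correlation filtering,
#' high-correlation lncRNA-mRNA pairing, and tripartite network assembly.
#'
#' @param counts named list of [count_matrix()] per class.
#' @param sequences a [sequence_set()].
#' @param cmp `c(test_group, reference_group)`.
#' @param config a [pipeline_config()].
#' @return list with the DE tables, candidate and pair tables, the three
#'   pair networks, the merged tripartite network and its stats.
#' @export
run_comparison <- function(counts, sequences, cmp, config) {
  de <- list()
  profiles <- list()
  for (cls in FEATURE_CLASSES) {
    sub <- subset_samples(counts[[cls]], cmp)
    res <- nb_test(sub, cmp[1], cmp[2],
                   allow_no_replicates = config$allow_no_replicates)
    res$fdr <- bh_adjust(res$p_value)
    de[[cls]] <- call_de(res, config$thresholds, cls)
    profiles[[cls]] <- expression_profiles(sub)
  }
  de_ids <- lapply(de, function(d) d$feature_id[d$call != "ns"])

  mir_seqs <- sequences[sequences$class == "miRNA", ]
  tgt_seqs <- sequences[sequences$class != "miRNA", ]
  candidates <- predict_targets(
    mir_seqs, tgt_seqs, min_score = config$min_score,
    de_mirnas = de_ids$miRNA,
    de_targets = c(de_ids$mRNA, de_ids$lncRNA))
  mm_cand <- candidates[candidates$target_class != "lncRNA", , drop = FALSE]
  ml_cand <- candidates[candidates$target_class == "lncRNA", , drop = FALSE]
  mm_pairs <- negative_filter(mm_cand, profiles$miRNA, profiles$mRNA,
                              r_max_neg = config$r_max_neg)
  ml_pairs <- negative_filter(ml_cand, profiles$miRNA, profiles$lncRNA,
                              r_max_neg = config$r_max_neg)
  lm_pairs <- lncrna_mrna_pairs(
    profiles$lncRNA[de_ids$lncRNA, , drop = FALSE],
    profiles$mRNA[de_ids$mRNA, , drop = FALSE],
    r_min = config$r_min)

  calls <- do.call(rbind, lapply(de, function(d)
    d[, c("feature_id", "class", "call")]))
  net_mm <- build_pair_network(mm_pairs, calls)
  net_ml <- build_pair_network(ml_pairs, calls)
  net_lm <- build_pair_network(lm_pairs, calls)
  tripartite <- merge_tripartite(net_mm, net_ml, net_lm)

  list(comparison = cmp, de = de, candidates = candidates,
       pairs = list(mirna_mrna = mm_pairs, mirna_lncrna = ml_pairs,
                    lncrna_mrna = lm_pairs),
       networks = list(mirna_mrna = net_mm, mirna_lncrna = net_ml,
                       lncrna_mrna = net_lm, tripartite = tripartite),
       stats = network_stats(tripartite, config$hub_quantile),
       profiles = profiles)
}

write_comparison <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in names(res$de))
    write_de_table(res$de[[cls]],
                   file.path(dir, sprintf("de_%s.tsv", tolower(cls))))
  write_pairs(res$candidates, file.path(dir, "target_candidates.tsv"))
  for (pc in names(res$pairs))
    write_pairs(res$pairs[[pc]], file.path(dir,
                                           sprintf("pairs_%s.tsv", pc)))
  for (nn in names(res$networks)) {
    write_network(res$networks[[nn]],
                  sif_path = file.path(dir, sprintf("network_%s.sif", nn)))
  }
  write_network(res$networks$tripartite,
                graphml_path = file.path(dir, "network_tripartite.graphml"),
                node_table_path = file.path(dir, "network_nodes.tsv"))
  st <- res$stats
  yaml::write_yaml(list(
    n_nodes = st$n_nodes, nodes_by_class = as.list(st$nodes_by_class),
    n_edges = st$n_edges, edges_by_type = as.list(st$edges_by_type),
    n_positive_pairs = st$n_positive_pairs,
    n_negative_pairs = st$n_negative_pairs,
    hubs = as.list(st$hubs)), file.path(dir, "network_stats.yaml"))
  invisible(NULL)
}

#' Evaluate pipeline output against planted ground truth
#'
#' Precision and recall of planted miRNA-mRNA, miRNA-lncRNA and
#' lncRNA-mRNA edges against the union of the recovered tripartite
#' networks, seed-site recall of the scanner on the planted sites, and
#' the empirical false-discovery proportion of the DE calls per class.
#'
#' @param results list of per-comparison results from [run_comparison()].
#' @param truth the `ground_truth` of the simulated cohort.
#' @param sequences the cohort [sequence_set()].
#' @return data.frame with columns metric and value.
#' @export
evaluate_against_truth <- function(results, truth, sequences) {
  found <- list(mirna_mrna = character(0), mirna_lncrna = character(0),
                lncrna_mrna = character(0))
  for (res in results) {
    for (et in names(found)) {
      e <- res$networks$tripartite$edges
      e <- e[e$edge_type == et, , drop = FALSE]
      found[[et]] <- union(found[[et]], paste(e$source, e$target))
    }
  }
  planted <- list(
    mirna_mrna = paste(truth$edges$mirna_mrna$mirna_id,
                       truth$edges$mirna_mrna$target_id),
    mirna_lncrna = paste(truth$edges$mirna_lncrna$mirna_id,
                         truth$edges$mirna_lncrna$target_id),
    lncrna_mrna = paste(truth$edges$lncrna_mrna$lncrna_id,
                        truth$edges$lncrna_mrna$mrna_id))
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value,
                                            stringsAsFactors = FALSE)
  for (et in names(planted)) {
    tp <- length(intersect(found[[et]], planted[[et]]))
    add(paste0(et, "_recall"),
        if (length(planted[[et]])) tp / length(planted[[et]]) else NA_real_)
    add(paste0(et, "_precision"),
        if (length(found[[et]])) tp / length(found[[et]]) else NA_real_)
  }
  # scanner recall of planted sites, independent of DE and correlation
  if (!is.null(truth$sites) && nrow(truth$sites) > 0) {
    seqs <- setNames(sequences$seq, sequences$id)
    hit <- vapply(seq_len(nrow(truth$sites)), function(i) {
      s <- truth$sites[i, ]
      sites <- find_seed_sites(seqs[[s$mirna_id]], seqs[[s$target_id]])
      any(sites$start == s$start & sites$site_type == "8mer")
    }, logical(1))
    add("site_recall", mean(hit))
  }
  # empirical false-discovery proportion of DE calls
  for (cls in FEATURE_CLASSES) {
    called <- character(0)
    false_called <- character(0)
    for (res in results) {
      d <- res$de[[cls]]
      cmp <- res$comparison
      true_de <- true_de_features(truth, cls, cmp[1], cmp[2])
      ids <- d$feature_id[d$call != "ns"]
      called <- c(called, paste(comparison_label(cmp), ids))
      false_called <- c(false_called,
                        paste(comparison_label(cmp), setdiff(ids, true_de)))
    }
    add(paste0("de_", tolower(cls), "_empirical_fdr"),
        if (length(called)) length(false_called) / length(called)
        else NA_real_)
  }
  do.call(rbind, rows)
}

#' Run the full integrative pipeline
#'
#' Simulates (or loads) the cohort, runs every configured comparison
#' through differential expression, target prediction, correlation
#' pairing, network assembly and enrichment, writes all artifacts under
#' `out_dir`, and returns them together with a checksum manifest. In
#' simulation mode a ground-truth evaluation report is also produced.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `results` (per comparison),
#'   `enrichment`, `evaluation` (simulation mode), `manifest`
#'   (data.frame of file, md5) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  simulated <- is.null(config$input)
  if (simulated) {
    cohort <- simulate_cohort(config$simulation)
  } else {
    cohort <- config$input
    cohort$truth <- NULL
  }
  counts <- cohort$counts
  sequences <- cohort$sequences
  annotation <- cohort$annotation

  input_dir <- file.path(out, "input")
  dir.create(input_dir, showWarnings = FALSE)
  for (cls in names(counts))
    write_counts(counts[[cls]],
                 file.path(input_dir, sprintf("counts_%s.tsv",
                                              tolower(cls))),
                 file.path(input_dir, "metadata.tsv"))
  write_fasta(sequences, file.path(input_dir, "sequences.fasta"))
  if (simulated) {
    for (et in names(cohort$truth$edges))
      write.table(cohort$truth$edges[[et]],
                  file.path(input_dir, sprintf("truth_edges_%s.tsv", et)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_echo <- cohort$config
    yaml::write_yaml(unclass(cfg_echo),
                     file.path(input_dir, "simulation_config.yaml"))
  }

  results <- list()
  enrichment <- list()
  for (cmp in config$comparisons) {
    label <- comparison_label(cmp)
    res <- tryCatch(
      run_comparison(counts, sequences, cmp, config),
      error = function(e) stop(sprintf(
        "pipeline stage 'comparison %s' failed: %s", label,
        conditionMessage(e)), call. = FALSE))
    cdir <- file.path(out, "comparisons", label)
    write_comparison(res, cdir)
    if (!is.null(annotation)) {
      background <- rownames(counts$mRNA$counts)[
        rowSums(subset_samples(counts$mRNA, cmp)$counts) > 0]
      de_genes <- intersect(
        res$de$mRNA$feature_id[res$de$mRNA$call != "ns"], background)
      enr <- enrich(de_genes, annotation, background,
                    p_threshold = config$enrich_p)
      write_enrichment(enr, file.path(cdir, "enrichment_mrna.tsv"))
      enrichment[[label]] <- enr
    }
    res$profiles <- NULL  # not serialized; drop from the returned object
    results[[label]] <- res
  }

  evaluation <- NULL
  if (simulated) {
    evaluation <- evaluate_against_truth(results, cohort$truth, sequences)
    write.table(evaluation, file.path(out, "evaluation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  files <- list.files(out, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files))),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(results = results, enrichment = enrichment,
                 evaluation = evaluation, manifest = manifest,
                 out_dir = out, truth = if (simulated) cohort$truth))
}
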