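# Readers and writers for the external formats of the pipeline:
# count tables + sample metadata (TSV), RNA sequences (FASTA),
# annotation / relation tables (TSV), and network exports (SIF, GraphML).
#
# TSV dialect throughout: tab-separated, UTF-8, '#'-prefixed comment lines
# skipped. All sequence/site coordinates exposed by this package are
# 0-based, half-open.

#' Construct a validated count matrix
#'
#' The basic expression container: a non-negative integer matrix of
#' features x samples, with one feature class per feature (mRNA, lncRNA or
#' miRNA) and one group label per sample.
#'
#' @param counts numeric matrix of non-negative integers with rownames
#'   (feature ids) and colnames (sample ids).
#' @param feature_class character; either a single class recycled to all
#'   features or one class per feature. Must be in
#'   `c("mRNA", "lncRNA", "miRNA")`.
#' @param sample_group character vector of group labels, one per sample.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `feature_class` (named by feature) and `sample_group` (named by
#'   sample).
#' @export
count_matrix <- function(counts, feature_class, sample_group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop(sprintf("duplicate feature id: %s",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    stop(sprintf("duplicate sample id: %s",
                 colnames(counts)[duplicated(colnames(counts))][1]))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite and numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "malformed count at feature '%s', sample '%s': %s (must be a non-negative integer)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  storage.mode(counts) <- "double"  # canonical storage; values stay integral
  if (length(feature_class) == 1)
    feature_class <- rep(feature_class, nrow(counts))
  if (length(feature_class) != nrow(counts))
    stop("feature_class must have length 1 or nrow(counts)")
  if (!all(feature_class %in% FEATURE_CLASSES))
    stop("feature_class values must be in {mRNA, lncRNA, miRNA}")
  if (length(sample_group) != ncol(counts))
    stop("sample_group must have one label per sample")
  structure(list(
    counts = counts,
    feature_class = setNames(as.character(feature_class), rownames(counts)),
    sample_group = setNames(as.character(sample_group), colnames(counts))
  ), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features (%s) x %d samples, groups: %s\n",
              nrow(x$counts),
              paste(unique(x$feature_class), collapse = "/"),
              ncol(x$counts),
              paste(unique(x$sample_group), collapse = ", ")))
  invisible(x)
}

#' Restrict a count matrix to the samples of selected groups
#'
#' @param cm a [count_matrix()].
#' @param groups character vector of group labels to keep.
#' @return A `count_matrix` containing only samples of those groups.
#' @export
subset_samples <- function(cm, groups) {
  stopifnot(inherits(cm, "count_matrix"))
  missing_g <- setdiff(groups, unique(cm$sample_group))
  if (length(missing_g) > 0)
    stop(sprintf("group(s) not present in count matrix: %s",
                 paste(missing_g, collapse = ", ")))
  keep <- names(cm$sample_group)[cm$sample_group %in% groups]
  count_matrix(cm$counts[, keep, drop = FALSE], cm$feature_class,
               cm$sample_group[keep])
}

#' Read a counts TSV plus sample metadata into a count matrix
#'
#' The counts file has a header row of sample ids and a first column of
#' feature ids; the metadata file has columns `sample_id` and `group`.
#' Samples present in the counts but absent from the metadata are an error.
#'
#' @param counts_path path to the counts TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param feature_class class label attached to all features in the file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, metadata_path, feature_class) {
  tab <- read.delim(counts_path, header = TRUE, sep = "\t",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file must have feature ids plus >=1 sample")
  ids <- as.character(tab[[1]])
  mat <- tab[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (any(is.na(v) & !is.na(mat[[j]])) || any(is.na(v)))
      stop(sprintf("malformed count in column '%s' (non-numeric cell)",
                   colnames(mat)[j]))
    mat[[j]] <- v
  }
  m <- as.matrix(mat)
  rownames(m) <- ids
  meta <- read.delim(metadata_path, header = TRUE, sep = "\t",
                     comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("metadata must have columns 'sample_id' and 'group'")
  absent <- setdiff(colnames(m), meta$sample_id)
  if (length(absent) > 0)
    stop(sprintf("sample(s) missing from metadata: %s",
                 paste(absent, collapse = ", ")))
  grp <- setNames(as.character(meta$group), meta$sample_id)[colnames(m)]
  count_matrix(m, feature_class, grp)
}

#' Write a count matrix as counts + metadata TSV
#'
#' Inverse of [read_counts()]: the round trip preserves counts, ids,
#' classes and group labels.
#'
#' @inheritParams subset_samples
#' @param counts_path,metadata_path output paths.
#' @export
write_counts <- function(cm, counts_path, metadata_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = names(cm$sample_group),
                     group = unname(cm$sample_group),
                     stringsAsFactors = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Construct a sequence set
#'
#' A flat container of RNA records: unique ids, sequences over
#' `{A,C,G,U}`, and a class label (`miRNA`, `mRNA_3utr` or `lncRNA`).
#'
#' @param id character vector of unique record ids.
#' @param seq character vector of RNA sequences (T is normalized to U,
#'   case to upper).
#' @param class single class label or one per record.
#' @return data.frame of class `sequence_set` with columns id, seq, class.
#' @export
sequence_set <- function(id, seq, class) {
  id <- as.character(id)
  seq <- chartr("T", "U", toupper(as.character(seq)))
  if (anyDuplicated(id))
    stop(sprintf("duplicate sequence id: %s", id[duplicated(id)][1]))
  if (any(nchar(seq) == 0))
    stop(sprintf("empty sequence for id: %s", id[nchar(seq) == 0][1]))
  check_rna_alphabet(seq, "sequence")
  if (length(class) == 1) class <- rep(class, length(id))
  if (!all(class %in% SEQ_CLASSES))
    stop("sequence class must be in {miRNA, mRNA_3utr, lncRNA}")
  structure(data.frame(id = id, seq = seq, class = class,
                       stringsAsFactors = FALSE),
            class = c("sequence_set", "data.frame"))
}

#' Read a FASTA file into a sequence set
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are upper-cased with T normalized to U.
#'
#' @param path FASTA file path.
#' @param class class label attached to all records.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, class) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  sequence_set(ids, as.character(ss), class)
}

#' Write a sequence set as FASTA
#'
#' @param ss a [sequence_set()].
#' @param path output FASTA path.
#' @export
write_fasta <- function(ss, path) {
  stopifnot(inherits(ss, "sequence_set"))
  x <- Biostrings::RNAStringSet(setNames(ss$seq, ss$id))
  Biostrings::writeXStringSet(x, path)
  invisible(NULL)
}

#' Read a gene-to-term annotation table
#'
#' Expects columns `term_id` and `gene_id`, with an optional `term_name`.
#' Terms with empty gene sets cannot arise from a well-formed file.
#'
#' @param path annotation TSV path.
#' @return An `annotation_map`: list with `terms` (named list of gene-id
#'   vectors) and `term_names` (named character, possibly empty).
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% colnames(tab)))
    stop("annotation must have columns 'term_id' and 'gene_id'")
  terms <- split(as.character(tab$gene_id), as.character(tab$term_id))
  terms <- lapply(terms, unique)
  nm <- character(0)
  if ("term_name" %in% colnames(tab)) {
    first <- !duplicated(tab$term_id)
    nm <- setNames(as.character(tab$term_name[first]),
                   as.character(tab$term_id[first]))
  }
  annotation_map(terms, nm)
}

#' Construct an annotation map
#'
#' @param terms named list mapping term_id to a character vector of gene
#'   ids; empty term sets are an error.
#' @param term_names optional named character of human-readable term names.
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(terms, term_names = character(0)) {
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("terms must be a uniquely named list")
  if (any(lengths(terms) == 0))
    stop(sprintf("empty term set: %s",
                 names(terms)[lengths(terms) == 0][1]))
  structure(list(terms = lapply(terms, as.character),
                 term_names = term_names),
            class = "annotation_map")
}

#' Read a gene-gene or pathway-pathway relation table
#'
#' Expects columns `entity_a`, `entity_b` and, for gene relations, a
#' `relation_type` drawn from the closed vocabulary
#' `{exp, a, b, inh, c, com}`. Pathway-pathway tables may omit the type
#' column (`labeled = FALSE`).
#'
#' @param path relation TSV path.
#' @param labeled whether a `relation_type` column is required.
#' @return data.frame of class `relation_table`.
#' @export
read_relations <- function(path, labeled = TRUE) {
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("entity_a", "entity_b") %in% colnames(tab)))
    stop("relations must have columns 'entity_a' and 'entity_b'")
  if (labeled) {
    if (!"relation_type" %in% colnames(tab))
      stop("labeled relation table requires a 'relation_type' column")
    bad <- setdiff(unique(tab$relation_type), RELATION_TYPES)
    if (length(bad) > 0)
      stop(sprintf("unknown relation_type(s): %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(RELATION_TYPES, collapse = ", ")))
  } else {
    tab$relation_type <- NA_character_
  }
  structure(tab[, c("entity_a", "entity_b", "relation_type")],
            class = c("relation_table", "data.frame"))
}

# ---- network export -------------------------------------------------------

reg_network_to_igraph <- function(net) {
  stopifnot(inherits(net, "reg_network"))
  if (nrow(net$nodes) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = TRUE))
  }
  vertices <- data.frame(name = net$nodes$id, class = net$nodes$class,
                         direction = net$nodes$direction,
                         stringsAsFactors = FALSE)
  edges <- net$edges
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, nrow(vertices),
                              name = vertices$name, class = vertices$class,
                              direction = vertices$direction)
    return(g)
  }
  d <- data.frame(from = edges$source, to = edges$target,
                  edge_type = edges$edge_type,
                  r = as.numeric(edges$r),
                  align_score = as.numeric(edges$align_score),
                  stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(d, directed = TRUE, vertices = vertices)
}

igraph_to_reg_network <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) {
    return(reg_network(empty_nodes(), empty_edges(), drop_isolated = FALSE))
  }
  na_nan <- function(x) { x[is.nan(x)] <- NA_real_; x }
  nodes <- data.frame(id = igraph::V(g)$name,
                      class = igraph::V(g)$class,
                      direction = igraph::V(g)$direction,
                      stringsAsFactors = FALSE)
  if (igraph::ecount(g) == 0) {
    return(reg_network(nodes, empty_edges(), drop_isolated = FALSE))
  }
  ends <- igraph::as_edgelist(g)
  edges <- data.frame(source = ends[, 1], target = ends[, 2],
                      edge_type = igraph::E(g)$edge_type,
                      r = na_nan(as.numeric(igraph::E(g)$r)),
                      align_score = na_nan(as.numeric(igraph::E(g)$align_score)),
                      stringsAsFactors = FALSE)
  reg_network(nodes, edges, drop_isolated = FALSE)
}

#' Write a regulatory network in Cytoscape-compatible formats
#'
#' Writes a SIF file (`source<TAB>edge_type<TAB>target`), a GraphML file
#' carrying node attributes (class, regulation direction) and edge
#' attributes (Pearson r, alignment score), and a node table TSV with
#' id, class, direction and degree. Writing then re-reading the GraphML
#' with [read_network()] reproduces an isomorphic attributed graph.
#'
#' @param net a [reg_network()].
#' @param sif_path,graphml_path,node_table_path output paths; any may be
#'   `NULL` to skip that format.
#' @export
write_network <- function(net, sif_path = NULL, graphml_path = NULL,
                          node_table_path = NULL) {
  stopifnot(inherits(net, "reg_network"))
  if (!is.null(sif_path)) {
    lines <- character(0)
    if (nrow(net$edges) > 0)
      lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$edge_type,
                       net$edges$target)
    writeLines(lines, sif_path)
  }
  if (!is.null(graphml_path)) {
    g <- reg_network_to_igraph(net)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(node_table_path)) {
    deg <- node_degrees(net)
    tab <- data.frame(id = net$nodes$id, class = net$nodes$class,
                      direction = net$nodes$direction,
                      degree = as.integer(deg[net$nodes$id]),
                      stringsAsFactors = FALSE)
    write.table(tab, node_table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a regulatory network back from GraphML
#'
#' @param graphml_path path written by [write_network()].
#' @return A [reg_network()].
#' @export
read_network <- function(graphml_path) {
  g <- igraph::read_graph(graphml_path, format = "graphml")
  igraph_to_reg_network(g)
}

#' Write a gene-act or pathway-act network as SIF
#'
#' Gene relations are encoded as `gene_act:<relation>` edge types;
#' unlabeled pathway links as `pathway_act`.
#'
#' @param net an `act_network` from [act_network()].
#' @param sif_path output path.
#' @export
write_act_network <- function(net, sif_path) {
  stopifnot(inherits(net, "act_network"))
  type <- ifelse(is.na(net$edges$relation_type), "pathway_act",
                 paste0("gene_act:", net$edges$relation_type))
  lines <- character(0)
  if (nrow(net$edges) > 0)
    lines <- sprintf("%s\t%s\t%s", net$edges$entity_a, type,
                     net$edges$entity_b)
  writeLines(lines, sif_path)
  invisible(NULL)
}
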