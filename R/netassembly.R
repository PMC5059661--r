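# Typed tripartite regulatory network: construction from pair tables,
# merging of the three pair-networks, and the summary statistics reported
# for such networks (node/edge counts per class/type, degrees, hubs).

empty_nodes <- function() {
  data.frame(id = character(0), class = character(0),
             direction = character(0), stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(source = character(0), target = character(0),
             edge_type = character(0), r = numeric(0),
             align_score = numeric(0), stringsAsFactors = FALSE)
}

edge_class_pattern <- list(
  mirna_mrna   = c(source = "miRNA",  target = "mRNA"),
  mirna_lncrna = c(source = "miRNA",  target = "lncRNA"),
  lncrna_mrna  = c(source = "lncRNA", target = "mRNA")
)

#' Construct a validated regulatory network
#'
#' Nodes are typed (miRNA / lncRNA / mRNA) and carry their regulation
#' direction (up / down); edges are typed (`mirna_mrna`, `mirna_lncrna`,
#' `lncrna_mrna`) and carry a Pearson r and/or an alignment score.
#' miRNA->target edges are directed from the miRNA; lncRNA-mRNA edges are
#' undirected in meaning and stored with the lncRNA as source.
#'
#' @param nodes data.frame with columns id, class, direction.
#' @param edges data.frame with columns source, target, edge_type and
#'   optional numeric r and align_score.
#' @param drop_isolated drop nodes that participate in no edge (the
#'   default, matching network assembly semantics).
#' @return An object of class `reg_network`.
#' @export
reg_network <- function(nodes, edges = empty_edges(), drop_isolated = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0) nodes <- empty_nodes()
  if (nrow(edges) == 0) edges <- empty_edges()
  if (!all(c("id", "class", "direction") %in% colnames(nodes)))
    stop("nodes must have columns id, class, direction")
  if (!"r" %in% colnames(edges)) edges$r <- NA_real_
  if (!"align_score" %in% colnames(edges)) edges$align_score <- NA_real_
  edges <- edges[, c("source", "target", "edge_type", "r", "align_score")]
  if (anyDuplicated(nodes$id))
    stop(sprintf("duplicate node id: %s",
                 nodes$id[duplicated(nodes$id)][1]))
  if (!all(nodes$class %in% FEATURE_CLASSES))
    stop("node class must be in {mRNA, lncRNA, miRNA}")
  if (!all(nodes$direction %in% c("up", "down")))
    stop("node direction must be 'up' or 'down'")
  if (nrow(edges) > 0) {
    if (!all(edges$edge_type %in% EDGE_TYPES))
      stop("edge_type must be in {mirna_mrna, mirna_lncrna, lncrna_mrna}")
    missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing_ep) > 0)
      stop(sprintf("edge endpoint not among nodes: %s", missing_ep[1]))
    if (any(edges$source == edges$target))
      stop("self-loops are not allowed")
    cls <- setNames(nodes$class, nodes$id)
    for (et in unique(edges$edge_type)) {
      pat <- edge_class_pattern[[et]]
      sel <- edges$edge_type == et
      ok <- cls[edges$source[sel]] == pat["source"] &
        cls[edges$target[sel]] == pat["target"]
      if (!all(ok))
        stop(sprintf("edge of type %s with wrong endpoint classes: %s -> %s",
                     et, edges$source[sel][!ok][1], edges$target[sel][!ok][1]))
    }
    key <- edge_key(edges)
    if (anyDuplicated(key))
      stop(sprintf("duplicate edge: %s", key[duplicated(key)][1]))
  }
  if (drop_isolated && nrow(nodes) > 0) {
    used <- unique(c(edges$source, edges$target))
    nodes <- nodes[nodes$id %in% used, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "reg_network")
}

# Canonical identity of an edge: unordered endpoint pair + type.
edge_key <- function(edges) {
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  paste(a, b, edges$edge_type, sep = "\r")
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("reg_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

pair_class_to_edge_type <- c("miRNA-mRNA" = "mirna_mrna",
                             "miRNA-lncRNA" = "mirna_lncrna",
                             "lncRNA-mRNA" = "lncrna_mrna")

pair_class_to_node_class <- list(
  "miRNA-mRNA" = c("miRNA", "mRNA"),
  "miRNA-lncRNA" = c("miRNA", "lncRNA"),
  "lncRNA-mRNA" = c("lncRNA", "mRNA")
)

#' Build a typed pair-network from a pair table
#'
#' Takes either high-correlation lncRNA-mRNA pairs (from
#' [lncrna_mrna_pairs()]) or negatively correlated miRNA-target
#' candidates (from [negative_filter()]), attaches each member's
#' differential-expression direction, deduplicates edges, and drops
#' isolated nodes.
#'
#' @param pairs data.frame with columns feature_a, feature_b, pair_class
#'   and optional r / align_score.
#' @param de_calls data.frame with columns feature_id and call; every pair
#'   member must be called up or down.
#' @return A [reg_network()].
#' @export
build_pair_network <- function(pairs, de_calls) {
  if (is.null(pairs) || nrow(pairs) == 0)
    return(reg_network(empty_nodes(), empty_edges(), drop_isolated = FALSE))
  stopifnot(all(c("feature_a", "feature_b", "pair_class") %in%
                  colnames(pairs)))
  if (!all(pairs$pair_class %in% PAIR_CLASSES))
    stop("pair_class must be in {lncRNA-mRNA, miRNA-mRNA, miRNA-lncRNA}")
  calls <- setNames(de_calls$call, de_calls$feature_id)
  members <- unique(c(pairs$feature_a, pairs$feature_b))
  bad <- members[!(members %in% names(calls)) |
                   !(calls[members] %in% c("up", "down"))]
  if (length(bad) > 0)
    stop(sprintf("pair member without an up/down DE call: %s", bad[1]))
  cls_a <- vapply(pairs$pair_class,
                  function(pc) pair_class_to_node_class[[pc]][1], character(1))
  cls_b <- vapply(pairs$pair_class,
                  function(pc) pair_class_to_node_class[[pc]][2], character(1))
  nodes <- unique(data.frame(
    id = c(pairs$feature_a, pairs$feature_b),
    class = c(cls_a, cls_b),
    stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$id))
    stop(sprintf("feature id used with two classes: %s",
                 nodes$id[duplicated(nodes$id)][1]))
  nodes$direction <- unname(calls[nodes$id])
  edges <- data.frame(
    source = pairs$feature_a,
    target = pairs$feature_b,
    edge_type = unname(pair_class_to_edge_type[pairs$pair_class]),
    r = if ("r" %in% colnames(pairs)) as.numeric(pairs$r) else NA_real_,
    align_score = if ("align_score" %in% colnames(pairs))
      as.numeric(pairs$align_score) else NA_real_,
    stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
  reg_network(nodes, edges)
}

#' Merge the three pair-networks into the tripartite network
#'
#' Union of nodes and edges of the miRNA-mRNA, miRNA-lncRNA and
#' lncRNA-mRNA networks. Node attributes (class, direction) must agree
#' wherever a node is shared; a conflict is an error naming the node.
#' Merging is commutative, associative and idempotent.
#'
#' @param ... two or more [reg_network()] objects.
#' @return The merged [reg_network()].
#' @export
merge_tripartite <- function(...) {
  nets <- list(...)
  stopifnot(length(nets) >= 1, all(vapply(nets, inherits, logical(1),
                                          "reg_network")))
  nodes <- unique(do.call(rbind, lapply(nets, `[[`, "nodes")))
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1]
    stop(sprintf(
      "conflicting class/direction attributes for shared node: %s", dup))
  }
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  if (nrow(edges) > 0)
    edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
  reg_network(nodes, edges)
}

node_degrees <- function(net) {
  deg <- setNames(rep(0L, nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges$source, net$edges$target))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Summary statistics of a regulatory network
#'
#' Node counts per class, edge counts per type, positive/negative
#' correlation-pair counts, per-node degrees, and hub nodes (degree at or
#' above the given quantile of the degree distribution).
#'
#' @param net a [reg_network()].
#' @param hub_quantile degree quantile defining hubs (default 0.9).
#' @return A list of class `network_stats`.
#' @export
network_stats <- function(net, hub_quantile = 0.9) {
  stopifnot(inherits(net, "reg_network"))
  nodes_by_class <- setNames(rep(0L, length(FEATURE_CLASSES)),
                             FEATURE_CLASSES)
  tc <- table(net$nodes$class)
  nodes_by_class[names(tc)] <- as.integer(tc)
  edges_by_type <- setNames(rep(0L, length(EDGE_TYPES)), EDGE_TYPES)
  te <- table(net$edges$edge_type)
  edges_by_type[names(te)] <- as.integer(te)
  r <- net$edges$r
  deg <- node_degrees(net)
  hubs <- character(0)
  if (length(deg) > 0) {
    thr <- quantile(deg, hub_quantile, names = FALSE)
    hubs <- names(deg)[deg >= thr]
  }
  structure(list(
    n_nodes = nrow(net$nodes),
    nodes_by_class = nodes_by_class,
    n_edges = nrow(net$edges),
    edges_by_type = edges_by_type,
    n_positive_pairs = sum(!is.na(r) & r > 0),
    n_negative_pairs = sum(!is.na(r) & r < 0),
    degree = deg,
    hub_quantile = hub_quantile,
    hubs = hubs
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes (%s), %d edges (%s)\n",
              x$n_nodes,
              paste(sprintf("%s=%d", names(x$nodes_by_class),
                            x$nodes_by_class), collapse = ", "),
              x$n_edges,
              paste(sprintf("%s=%d", names(x$edges_by_type),
                            x$edges_by_type), collapse = ", ")))
  cat(sprintf("pairs: %d positive, %d negative; hubs (>= q%.2f): %s\n",
              x$n_positive_pairs, x$n_negative_pairs, x$hub_quantile,
              paste(x$hubs, collapse = ", ")))
  invisible(x)
}
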