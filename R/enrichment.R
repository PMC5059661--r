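# Over-representation analysis of DE / target gene sets against flat
# annotation terms (GO/KEGG-style) with the hypergeometric upper tail,
# plus gene-act and pathway-act networks induced from user-supplied
# relation tables.

#' Hypergeometric upper-tail probability
#'
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`: the probability
#' of drawing at least `k` annotated genes when `n` genes are drawn from a
#' universe of `N` containing `K` annotated ones.
#'
#' @param k annotated genes observed in the drawn set.
#' @param K annotated genes in the universe.
#' @param n size of the drawn set.
#' @param N universe size.
#' @return p in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (!(K >= 0 && K <= N && n >= 0 && n <= N && k >= 0 && k <= min(K, n)))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test of a gene set
#'
#' One result per annotation term with at least one hit (`k >= 1`):
#' the raw hypergeometric p, a BH-adjusted p across the tested terms, and
#' an `enriched` flag by raw `p < p_threshold` (with the FDR reported
#' alongside).
#'
#' @param gene_set character vector of genes of interest; must be a
#'   subset of `background`.
#' @param annotation an [annotation_map()].
#' @param background character vector: the gene universe.
#' @param p_threshold raw-p threshold for the enriched flag
#'   (default 0.05).
#' @return data.frame with columns term_id, term_name, k, K, n, N, p,
#'   fdr, enriched, ordered by p.
#' @export
enrich <- function(gene_set, annotation, background, p_threshold = 0.05) {
  stopifnot(inherits(annotation, "annotation_map"))
  background <- unique(as.character(background))
  gene_set <- unique(as.character(gene_set))
  offenders <- setdiff(gene_set, background)
  if (length(offenders) > 0)
    stop(sprintf("gene_set members outside the background: %s",
                 paste(head(offenders, 5), collapse = ", ")))
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE)
  if (length(gene_set) == 0) return(empty)
  N <- length(background)
  n <- length(gene_set)
  terms <- lapply(annotation$terms, intersect, background)
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), integer(1))
  keep <- k >= 1
  if (!any(keep)) return(empty)
  term_id <- names(terms)[keep]
  p <- vapply(which(keep), function(i) hypergeom_p(k[i], K[i], n, N),
              numeric(1))
  nm <- annotation$term_names[term_id]
  nm[is.na(nm)] <- ""
  res <- data.frame(
    term_id = term_id,
    term_name = unname(nm),
    k = unname(k[keep]), K = unname(K[keep]), n = n, N = N,
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    stringsAsFactors = FALSE)
  res$enriched <- res$p < p_threshold
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relation network induced on an entity set
#'
#' The induced subgraph of a relation table (gene-gene relations from a
#' STRING-style export, or unlabeled pathway-pathway links) on a set of
#' entities: edges whose two endpoints are both in the set, keeping the
#' relation type; isolated entities are dropped. For gene-act networks,
#' nodes can carry their DE direction for up/down colouring.
#'
#' @param entities character vector of entity ids (enriched pathways or
#'   DE genes).
#' @param relations a [read_relations()] table.
#' @param direction optional named character (`up`/`down`) per entity.
#' @return An object of class `act_network` with `nodes` (id, direction)
#'   and `edges` (entity_a, entity_b, relation_type).
#' @export
act_network <- function(entities, relations, direction = NULL) {
  stopifnot(inherits(relations, "relation_table"))
  entities <- unique(as.character(entities))
  sel <- relations$entity_a %in% entities &
    relations$entity_b %in% entities &
    relations$entity_a != relations$entity_b
  edges <- relations[sel, , drop = FALSE]
  ids <- unique(c(edges$entity_a, edges$entity_b))
  dirs <- rep(NA_character_, length(ids))
  if (!is.null(direction)) dirs <- unname(direction[ids])
  nodes <- data.frame(id = ids, direction = dirs, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = as.data.frame(edges)),
            class = "act_network")
}

#' Write enrichment results as TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
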