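test_that("pair networks attach DE direction, deduplicate and validate", {
  calls <- data.frame(
    feature_id = c("miR1", paste0("g", 1:9)),
    class = c("miRNA", rep("mRNA", 9)),
    call = c("up", rep("down", 9)), stringsAsFactors = FALSE)

  expect_equal(nrow(build_pair_network(
    data.frame(feature_a = character(0), feature_b = character(0),
               pair_class = character(0)), calls)$nodes), 0L)

  # one miRNA targeting nine mRNAs: a star of degree 9
  pairs <- data.frame(feature_a = "miR1", feature_b = paste0("g", 1:9),
                      pair_class = "miRNA-mRNA", r = -0.8,
                      stringsAsFactors = FALSE)
  net <- build_pair_network(pairs, calls)
  deg <- network_stats(net)$degree
  expect_equal(unname(deg["miR1"]), 9L)
  expect_equal(net$nodes$direction[net$nodes$id == "miR1"], "up")

  # duplicated input pair collapses to a single edge
  net2 <- build_pair_network(rbind(pairs, pairs[1, ]), calls)
  expect_equal(nrow(net2$edges), 9L)

  # a member without an up/down call is an error
  calls_bad <- calls
  calls_bad$call[calls_bad$feature_id == "g3"] <- "ns"
  expect_error(build_pair_network(pairs, calls_bad), "g3")
})

test_that("tripartite merge is union with attribute agreement", {
  mk <- function(pairs, calls) build_pair_network(pairs, calls)
  calls <- data.frame(
    feature_id = c("miR1", "lnc1", "g1", "g2"),
    class = c("miRNA", "lncRNA", "mRNA", "mRNA"),
    call = c("up", "down", "down", "up"), stringsAsFactors = FALSE)
  n1 <- mk(data.frame(feature_a = "miR1", feature_b = "lnc1",
                      pair_class = "miRNA-lncRNA", r = -0.7), calls)
  n2 <- mk(data.frame(feature_a = "lnc1", feature_b = "g1",
                      pair_class = "lncRNA-mRNA", r = 0.995), calls)
  n3 <- mk(data.frame(feature_a = "miR1", feature_b = "g2",
                      pair_class = "miRNA-mRNA", r = -0.9), calls)

  merged <- merge_tripartite(n1, n2, n3)
  expect_equal(nrow(merged$nodes), 4L)
  expect_equal(nrow(merged$edges), 3L)
  # the shared lncRNA appears once with both edge types incident
  lnc_edges <- merged$edges[merged$edges$source == "lnc1" |
                              merged$edges$target == "lnc1", ]
  expect_setequal(lnc_edges$edge_type, c("mirna_lncrna", "lncrna_mrna"))

  # disjoint components: node and edge counts add
  d <- merge_tripartite(n2, n3)
  expect_equal(nrow(d$nodes), nrow(n2$nodes) + nrow(n3$nodes))
  expect_equal(nrow(d$edges), nrow(n2$edges) + nrow(n3$edges))

  # conflicting direction for a shared node is an error naming it
  calls2 <- calls
  calls2$call[calls2$feature_id == "lnc1"] <- "up"
  n2b <- mk(data.frame(feature_a = "lnc1", feature_b = "g1",
                       pair_class = "lncRNA-mRNA", r = 0.995), calls2)
  expect_error(merge_tripartite(n1, n2b), "lnc1")
})

test_that("merge is commutative, associative and idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- random_toy_network(2, 2, 3, 4)
    b <- random_toy_network(2, 2, 3, 4)
    expect_equal(canonical_network(merge_tripartite(a, b)),
                 canonical_network(merge_tripartite(b, a)))
    c3 <- random_toy_network(2, 2, 3, 4)
    expect_equal(
      canonical_network(merge_tripartite(merge_tripartite(a, b), c3)),
      canonical_network(merge_tripartite(a, merge_tripartite(b, c3))))
    expect_equal(canonical_network(merge_tripartite(a, a)),
                 canonical_network(a))
  }
})

test_that("network statistics satisfy the partition invariants", {
  empty <- reg_network(empty_nodes())
  st0 <- network_stats(empty)
  expect_equal(st0$n_nodes, 0L)
  expect_equal(st0$n_edges, 0L)
  expect_equal(sum(st0$nodes_by_class), 0L)

  for (seed in 1:5) {
    set.seed(seed)
    net <- random_toy_network(4, 4, 6, 12)
    st <- network_stats(net)
    expect_equal(sum(st$nodes_by_class), st$n_nodes)
    expect_equal(sum(st$edges_by_type), st$n_edges)
    expect_equal(st$n_positive_pairs + st$n_negative_pairs,
                 sum(!is.na(net$edges$r) & net$edges$r != 0))
    # degree oracle: recount from the edge list
    deg_oracle <- table(c(net$edges$source, net$edges$target))
    expect_equal(unname(st$degree[names(deg_oracle)]),
                 as.integer(deg_oracle))
    expect_true(all(st$degree[st$hubs] >=
                      quantile(st$degree, 0.9, names = FALSE)))
  }
})

test_that("validation rejects malformed networks", {
  nodes <- data.frame(id = c("a", "b"), class = c("miRNA", "mRNA"),
                      direction = c("up", "down"))
  expect_error(reg_network(nodes, data.frame(
    source = "a", target = "a", edge_type = "mirna_mrna")), "self-loop")
  expect_error(reg_network(nodes, data.frame(
    source = "a", target = "c", edge_type = "mirna_mrna")), "endpoint")
  expect_error(reg_network(nodes, data.frame(
    source = "b", target = "a", edge_type = "mirna_mrna")), "classes")
})
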