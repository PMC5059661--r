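test_that("count TSV parsing validates values and metadata coverage", {
  counts <- file.path(tempdir(), "c.tsv")
  meta <- file.path(tempdir(), "m.tsv")
  writeLines(c("# expression matrix",
               "feature\ts1\ts2", "g1\t3\t0", "g2\t10\t7", "g3\t1\t2"),
             counts)
  writeLines(c("sample_id\tgroup", "s1\tA", "s2\tB"), meta)
  cm <- read_counts(counts, meta, "mRNA")
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(unname(cm$sample_group), c("A", "B"))
  expect_equal(unname(cm$feature_class), rep("mRNA", 3))
  expect_equal(cm$counts["g2", "s2"], 7)

  writeLines(c("feature\ts1\ts2", "g1\t3\t-4"), counts)
  expect_error(read_counts(counts, meta, "mRNA"), "g1.*s2|malformed")

  writeLines(c("feature\ts1\ts2", "g1\t3\t4"), counts)
  writeLines(c("sample_id\tgroup", "s1\tA"), meta)
  expect_error(read_counts(counts, meta, "mRNA"), "s2")

  writeLines(c("feature\ts1\ts2", "g1\t3\t4", "g1\t1\t1"), counts)
  writeLines(c("sample_id\tgroup", "s1\tA", "s2\tB"), meta)
  expect_error(read_counts(counts, meta, "mRNA"), "duplicate")
})

test_that("count matrix round trip is the identity", {
  set.seed(11)
  m <- matrix(rpois(40, 20), 8, 5,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%d", 1:5)))
  cm <- count_matrix(m, "lncRNA", rep(c("A", "B"), c(2, 3)))
  cp <- file.path(tempdir(), "rt_counts.tsv")
  mp <- file.path(tempdir(), "rt_meta.tsv")
  write_counts(cm, cp, mp)
  back <- read_counts(cp, mp, "lncRNA")
  expect_equal(back$counts, cm$counts)
  expect_equal(back$feature_class, cm$feature_class)
  expect_equal(back$sample_group, cm$sample_group)
})

test_that("FASTA reading normalizes and validates records", {
  fa <- file.path(tempdir(), "a.fasta")
  writeLines(c(">m1 some description", "UGAGGUAG"), fa)
  ss <- read_fasta(fa, "miRNA")
  expect_equal(ss$id, "m1")
  expect_equal(nchar(ss$seq), 8L)

  writeLines(c(">g1", "acgt"), fa)
  expect_equal(read_fasta(fa, "lncRNA")$seq, "ACGU")

  writeLines(c(">x", "ACGU", ">x", "GGGG"), fa)
  expect_error(read_fasta(fa, "miRNA"), "duplicate")
})

test_that("FASTA round trip preserves id/sequence pairs up to T->U", {
  set.seed(3)
  ss <- sequence_set(sprintf("r%d", 1:6),
                     chartr("U", "T", random_rna(6, 30)),  # read as DNA-ish
                     "mRNA_3utr")
  fa <- file.path(tempdir(), "rt.fasta")
  write_fasta(ss, fa)
  back <- read_fasta(fa, "mRNA_3utr")
  expect_equal(back$id, ss$id)
  expect_equal(back$seq, ss$seq)
})

test_that("SIF lines encode source, type and target", {
  net <- reg_network(
    data.frame(id = c("miR1", "gene1"), class = c("miRNA", "mRNA"),
               direction = c("up", "down")),
    data.frame(source = "miR1", target = "gene1",
               edge_type = "mirna_mrna", r = -0.9, align_score = 145))
  sif <- file.path(tempdir(), "one.sif")
  write_network(net, sif_path = sif)
  expect_equal(readLines(sif), "miR1\tmirna_mrna\tgene1")

  empty <- reg_network(empty_nodes())
  write_network(empty, sif_path = sif)
  expect_equal(length(readLines(sif)), 0L)
})

test_that("GraphML round trip preserves the attributed graph", {
  gml <- file.path(tempdir(), "net.graphml")

  empty <- reg_network(empty_nodes())
  write_network(empty, graphml_path = gml)
  expect_equal(nrow(read_network(gml)$nodes), 0L)

  for (seed in 1:5) {
    set.seed(seed)
    net <- random_toy_network(3, 3, 4, 8)
    write_network(net, graphml_path = gml)
    back <- read_network(gml)
    expect_equal(canonical_network(back), canonical_network(net))
  }
})

test_that("node table carries class, direction and degree", {
  set.seed(9)
  net <- random_toy_network()
  nt <- file.path(tempdir(), "nodes.tsv")
  write_network(net, node_table_path = nt)
  tab <- read.delim(nt)
  expect_setequal(tab$id, net$nodes$id)
  deg <- table(c(net$edges$source, net$edges$target))
  expect_equal(tab$degree[match(names(deg), tab$id)], as.integer(deg))
})

test_that("annotation and relation readers enforce their vocabularies", {
  ann <- file.path(tempdir(), "ann.tsv")
  writeLines(c("term_id\tgene_id\tterm_name",
               "T1\tg1\talpha", "T1\tg2\talpha", "T2\tg3\tbeta"), ann)
  am <- read_annotation(ann)
  expect_setequal(am$terms$T1, c("g1", "g2"))
  expect_equal(unname(am$term_names["T2"]), "beta")

  rel <- file.path(tempdir(), "rel.tsv")
  writeLines(c("entity_a\tentity_b\trelation_type", "A\tB\ta", "B\tC\tinh"),
             rel)
  rt <- read_relations(rel)
  expect_equal(rt$relation_type, c("a", "inh"))
  writeLines(c("entity_a\tentity_b\trelation_type", "A\tB\tzzz"), rel)
  expect_error(read_relations(rel), "zzz")
})
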