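small_cfg <- function(...) {
  args <- list(n_mrna = 60, n_lncrna = 12, n_mirna = 6,
               n_mirna_mrna_edges = 5, n_mirna_lncrna_edges = 2,
               n_lncrna_mrna_edges = 3)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_per_group = 2), "n_per_group")
  expect_error(simulation_config(repression_factor = 0), "repression_factor")
  expect_error(simulation_config(dispersion = -1), "dispersion")
  expect_error(simulation_config(fc_magnitude = 1), "fc_magnitude")
  expect_error(simulation_config(n_mrna = 10, n_mirna_mrna_edges = 20),
               "n_mirna_mrna_edges")
})

test_that("the cohort is fully reproducible from its seed", {
  c1 <- simulate_cohort(small_cfg(rng_seed = 5))
  c2 <- simulate_cohort(small_cfg(rng_seed = 5))
  expect_identical(c1$counts$mRNA$counts, c2$counts$mRNA$counts)
  expect_identical(c1$counts$miRNA$counts, c2$counts$miRNA$counts)
  expect_identical(c1$truth$edges, c2$truth$edges)
  expect_identical(c1$annotation$terms, c2$annotation$terms)
  f1 <- file.path(tempdir(), "d1.fasta")
  f2 <- file.path(tempdir(), "d2.fasta")
  write_fasta(c1$sequences, f1)
  write_fasta(c2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical FASTA
})

test_that("repression factor 1 leaves planted targets at baseline", {
  sim <- simulate_counts(small_cfg(repression_factor = 1, rng_seed = 3))
  tg <- sim$truth$edges$mirna_mrna$target_id
  E <- sim$truth$group_effect$mRNA[tg, , drop = FALSE]
  expect_true(all(abs(E - 1) < 1e-12))
})

test_that("zero dispersion gives the Poisson limit (variance ~ mean)", {
  cfg <- simulation_config(n_mrna = 40, n_lncrna = 1, n_mirna = 1,
                           groups = c("A", "B", "C"), n_per_group = 334,
                           dispersion = 0, frac_de = 0,
                           n_mirna_mrna_edges = 0, n_mirna_lncrna_edges = 0,
                           n_lncrna_mrna_edges = 0,
                           size_factor_range = c(1, 1), rng_seed = 9)
  m <- simulate_counts(cfg)$counts$mRNA$counts
  ratio <- apply(m, 1, var) / rowMeans(m)
  # var/mean ratio concentrates at 1 for Poisson draws (n = 1002)
  expect_true(all(abs(ratio - 1) < 0.25))
  expect_lt(abs(mean(ratio) - 1), 0.03)
})

test_that("non-DE feature means match the configured baseline", {
  cfg <- simulation_config(n_mrna = 30, n_lncrna = 1, n_mirna = 1,
                           groups = c("A", "B", "C"), n_per_group = 334,
                           frac_de = 0.1, fc_magnitude = 4,
                           n_mirna_mrna_edges = 0, n_mirna_lncrna_edges = 0,
                           n_lncrna_mrna_edges = 0,
                           size_factor_range = c(1, 1), rng_seed = 1)
  sim <- simulate_counts(cfg)
  m <- sim$counts$mRNA$counts
  n <- ncol(m)
  non_de <- setdiff(rownames(m), sim$truth$de_features$mRNA)
  for (f in non_de[1:10]) {
    mu <- sim$truth$baseline$mRNA[[f]]
    sdev <- sqrt(mu + cfg$dispersion * mu^2)
    expect_lt(abs(mean(m[f, ]) - mu), 4 * sdev / sqrt(n))
  }
})

test_that("planted sites are scanner-detectable and flanks are clean", {
  ch <- simulate_cohort(small_cfg(rng_seed = 8))
  seqs <- setNames(ch$sequences$seq, ch$sequences$id)
  st <- ch$truth$sites
  expect_equal(nrow(st), 7L)  # 5 mRNA + 2 lncRNA edges
  for (i in seq_len(nrow(st))) {
    found <- find_seed_sites(seqs[[st$mirna_id[i]]], seqs[[st$target_id[i]]])
    expect_true(any(found$start == st$start[i] & found$site_type == "8mer"))
  }

  # with no planted edges, no sequence contains any 6mer-or-better site
  ch0 <- simulate_cohort(small_cfg(n_mirna_mrna_edges = 0,
                                   n_mirna_lncrna_edges = 0,
                                   rng_seed = 8))
  mir <- ch0$sequences[ch0$sequences$class == "miRNA", ]
  tgt <- ch0$sequences[ch0$sequences$class != "miRNA", ]
  hits <- predict_targets(mir, tgt, min_score = 0)
  expect_equal(nrow(hits), 0L)
})

test_that("repression induces negative miRNA-target correlation across seeds", {
  neg <- logical(50)
  for (s in seq_along(neg)) {
    cfg <- simulation_config(n_mrna = 40, n_lncrna = 5, n_mirna = 5,
                             n_per_group = 5, repression_factor = 0.25,
                             n_mirna_mrna_edges = 6,
                             n_mirna_lncrna_edges = 0,
                             n_lncrna_mrna_edges = 0, rng_seed = 200 + s)
    sim <- simulate_counts(cfg)
    pm <- expression_profiles(sim$counts$miRNA)
    pg <- expression_profiles(sim$counts$mRNA)
    e <- sim$truth$edges$mirna_mrna
    r <- vapply(seq_len(nrow(e)), function(i) {
      pearson(pm[e$mirna_id[i], ], pg[e$target_id[i], ])
    }, numeric(1))
    neg[s] <- median(r, na.rm = TRUE) < 0
  }
  expect_gte(mean(neg), 0.95)
})

test_that("latent factor drives planted lncRNA-mRNA pairs to high |r|", {
  ch <- simulate_counts(simulation_config(rng_seed = 1))
  pl <- expression_profiles(ch$counts$lncRNA)
  pg <- expression_profiles(ch$counts$mRNA)
  e <- ch$truth$edges$lncrna_mrna
  r <- vapply(seq_len(nrow(e)), function(i) {
    pearson(pl[e$lncrna_id[i], ], pg[e$mrna_id[i], ])
  }, numeric(1))
  expect_gte(mean(abs(r)), 0.9)
  # planted sign is realized
  expect_true(all(sign(r) == ifelse(e$sign == "positive", 1, -1)))
})

test_that("simulated annotation plants one enriched term of matched size", {
  ch <- simulate_counts(small_cfg(rng_seed = 4))
  ann <- simulate_annotation(small_cfg(rng_seed = 4), ch$truth)
  expect_equal(length(ann$terms), 10L)
  sizes <- lengths(ann$terms)
  expect_true(all(sizes == sizes[1]))
  planted <- attr(ann, "planted_term")
  de <- ch$truth$de_features$mRNA
  expect_gte(length(intersect(ann$terms[[planted]], de)),
             round(0.8 * length(de)))

  # frac 1, background 0: the enriched term is exactly the DE set
  cfg1 <- small_cfg(ann_frac_de = 1, ann_background = 0, rng_seed = 4)
  ann1 <- simulate_annotation(cfg1, ch$truth)
  expect_setequal(ann1$terms[[attr(ann1, "planted_term")]], de)
})
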