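toy_cm <- function(m, groups) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  count_matrix(m, "mRNA", groups)
}

test_that("size factors follow the median-of-ratios construction", {
  m <- matrix(c(10, 20, 5, 40, 8,
                10, 20, 5, 40, 8), ncol = 2,
              dimnames = list(sprintf("f%d", 1:5), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 5, 40, 8), b = 2 * c(10, 20, 5, 40, 8))
  rownames(m2) <- sprintf("f%d", 1:5)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # a row of zeros is excluded from the reference set
  m3 <- rbind(m2, f6 = c(0, 0))
  expect_equal(size_factors(m3), size_factors(m2))

  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "infeasible")
})

test_that("size factors match the independent definition on random fixtures", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rpois(60, 30), 10, 6)
    dimnames(m) <- list(sprintf("f%d", 1:10), sprintf("s%d", 1:6))
    expect_equal(unname(size_factors(m)), unname(oracle_size_factors(m)))
  }
})

test_that("exact NB test is symmetric and handles degenerate zeros", {
  # identical columns: size factors are 1 and both group totals agree
  m <- rbind(f1 = rep(8, 6), f2 = rep(0, 6), f3 = rep(30, 6))
  colnames(m) <- sprintf("s%d", 1:6)
  cm <- toy_cm(m, rep(c("A", "B"), each = 3))
  res <- nb_test(cm, "A", "B")
  expect_equal(res$p_value[1], 1)           # identical counts in both groups
  expect_equal(res$fold_change[1], 1)
  expect_equal(res$p_value[2], 1)           # all-zero feature
  expect_equal(res$log2fc[2], 0)            # pseudocount rule
})

test_that("exact NB p matches brute-force enumeration on a toy feature", {
  m <- rbind(f1 = c(10, 12, 50, 55),
             f2 = c(30, 30, 30, 30))  # keeps size factors well-defined
  colnames(m) <- sprintf("s%d", 1:4)
  cm <- toy_cm(m, c("A", "A", "B", "B"))
  res <- nb_test(cm, "A", "B")
  # reconstruct the test's NB parameters from the definition
  sf <- oracle_size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  q <- mean(norm[1, ])
  v <- (var(norm[1, 1:2]) + var(norm[1, 3:4])) / 2
  alpha <- max((v - q) / q^2, 1e-8)
  p_oracle <- oracle_exact_p(round(sum(norm[1, 1:2])),
                             round(sum(norm[1, 3:4])),
                             mu_a = 2 * q, size_a = 2 / alpha,
                             mu_b = 2 * q, size_b = 2 / alpha)
  expect_equal(res$p_value[1], p_oracle, tolerance = 1e-10)
})

test_that("p-values are invariant to compensated column scaling", {
  set.seed(5)
  m <- matrix(rnbinom(120, mu = 50, size = 10), 20, 6)
  dimnames(m) <- list(sprintf("f%d", 1:20), sprintf("s%d", 1:6))
  cm <- toy_cm(m, rep(c("A", "B"), each = 3))
  sf0 <- rep(1, 6)
  p0 <- nb_test(cm, "A", "B", sf = sf0)$p_value
  m2 <- m
  m2[, 1] <- m[, 1] * 3
  cm2 <- toy_cm(m2, rep(c("A", "B"), each = 3))
  sf1 <- sf0
  sf1[1] <- 3  # the scaled column's true size factor absorbs the 3
  p1 <- nb_test(cm2, "A", "B", sf = sf1)$p_value
  expect_identical(p1, p0)
})

test_that("single-sample groups require the blind-dispersion opt-in", {
  m <- matrix(rpois(8, 40) + 1, 4, 2,
              dimnames = list(sprintf("f%d", 1:4), c("s1", "s2")))
  cm <- toy_cm(m, c("A", "B"))
  expect_error(nb_test(cm, "A", "B"), "allow_no_replicates")
  expect_warning(res <- nb_test(cm, "A", "B", allow_no_replicates = TRUE),
                 "blind")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("BH adjustment matches the step-up definition and is order-invariant", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), oracle_bh(p))
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("DE calls follow the class-specific rules", {
  thr <- de_thresholds()
  mk <- function(fc, fdr, p) data.frame(
    feature_id = "f", class = "mRNA", base_mean = 10, mean_a = 1,
    mean_b = 1, fold_change = fc, log2fc = log2(fc), p_value = p,
    fdr = fdr)
  expect_equal(call_de(mk(1.6, 0.01, 0.001), thr, "mRNA")$call, "up")
  expect_equal(call_de(mk(1.6, 0.2, 0.001), thr, "mRNA")$call, "ns")
  expect_equal(call_de(mk(0.5, 0.01, 0.001), thr, "lncRNA")$call, "down")
  # miRNA rule: |log2fc| and raw p
  mi <- function(l2, p) data.frame(
    feature_id = "f", class = "miRNA", base_mean = 10, mean_a = 1,
    mean_b = 1, fold_change = 2^l2, log2fc = l2, p_value = p, fdr = 1)
  expect_equal(call_de(mi(1.5, 0.01), thr, "miRNA")$call, "up")
  expect_equal(call_de(mi(0.9, 0.001), thr, "miRNA")$call, "ns")
  expect_equal(call_de(mi(-1.4, 0.02), thr, "miRNA")$call, "down")
  expect_error(call_de(mk(2, 0.01, 0.01), thr, "rRNA"), "unknown")
})
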