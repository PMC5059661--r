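# Independent oracles used to verify the package's computational paths.
# Each is written from the mathematical definition, without reuse of the
# implementation's code path.

# Exhaustive-enumeration two-sided exact NB test: probability of all
# splits of the observed total no more likely than the observed one.
# The pmf comes from stats::dnbinom; the enumeration, the tie rule and
# the summation are written out naively.
oracle_exact_p <- function(ka, kb, mu_a, size_a, mu_b, size_b) {
  ks <- ka + kb
  if (ks == 0) return(1)
  probs <- numeric(ks + 1)
  for (a in 0:ks) {
    probs[a + 1] <- dnbinom(a, mu = mu_a, size = size_a) *
      dnbinom(ks - a, mu = mu_b, size = size_b)
  }
  obs <- probs[ka + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]) / sum(probs))
}

# Median-of-ratios size factors from the definition, independent of
# cernanet::size_factors.
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  keep <- geo > 0 & is.finite(geo)
  apply(m, 2, function(col) median(col[keep] / geo[keep]))
}

# Direct BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-pass product-moment correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive-window seed-site oracle: tests every target window of
# length 6/7/8 for string equality with the four class definitions, then
# reports each seed-core anchor once at its best class.
oracle_sites <- function(mir, tgt) {
  rc <- function(s) cernanet::rna_revcomp(s)
  w6 <- rc(substr(mir, 2, 7))
  w7m8 <- rc(substr(mir, 2, 8))
  w7a1 <- paste0(w6, "A")
  w8 <- paste0(w7m8, "A")
  tl <- nchar(tgt)
  out <- list()
  for (anchor in 0:(tl - 6)) {            # 0-based start of the 6mer core
    if (substr(tgt, anchor + 1, anchor + 6) != w6) next
    is8 <- anchor >= 1 && anchor + 7 <= tl &&
      substr(tgt, anchor, anchor + 7) == w8
    is7m8 <- anchor >= 1 &&
      substr(tgt, anchor, anchor + 6) == w7m8
    is7a1 <- anchor + 7 <= tl &&
      substr(tgt, anchor + 1, anchor + 7) == w7a1
    if (is8) {
      out[[length(out) + 1]] <- data.frame(start = anchor - 1,
                                           end = anchor + 7,
                                           site_type = "8mer")
    } else if (is7m8) {
      out[[length(out) + 1]] <- data.frame(start = anchor - 1,
                                           end = anchor + 6,
                                           site_type = "7mer-m8")
    } else if (is7a1) {
      out[[length(out) + 1]] <- data.frame(start = anchor,
                                           end = anchor + 7,
                                           site_type = "7mer-A1")
    } else {
      out[[length(out) + 1]] <- data.frame(start = anchor,
                                           end = anchor + 6,
                                           site_type = "6mer")
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Top-down memoized affine local-alignment oracle. States: M = alignment
# ending in a pairing of mir[i] with (reversed) window base j; X / Y =
# ending in a gap consuming a window base / a miRNA base.
oracle_align <- function(mir, window, match = 5, wobble = 2,
                         mismatch = -3, gap_open = -8, gap_extend = -2) {
  m <- strsplit(mir, "", fixed = TRUE)[[1]]
  w <- rev(strsplit(window, "", fixed = TRUE)[[1]])
  n <- length(m); k <- length(w)
  ps <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "C" && b == "G") || (a == "G" && b == "C")) return(match)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(wobble)
    mismatch
  }
  memo <- new.env(parent = emptyenv())
  M <- function(i, j) {
    if (i < 1 || j < 1) return(-Inf)
    key <- paste0("M", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- ps(m[i], w[j]) * (if (i >= 2 && i <= 8) 2 else 1)
    v <- s + max(0, M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1))
    memo[[key]] <- v
    v
  }
  X <- function(i, j) {
    if (j < 1) return(-Inf)
    key <- paste0("X", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(M(i, j - 1) + gap_open, X(i, j - 1) + gap_extend)
    memo[[key]] <- v
    v
  }
  Y <- function(i, j) {
    if (i < 1) return(-Inf)
    key <- paste0("Y", i, ".", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(M(i - 1, j) + gap_open, Y(i - 1, j) + gap_extend)
    memo[[key]] <- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) best <- max(best, M(i, j))
  best
}

# Random valid attributed regulatory network for round-trip and merge
# property tests.
random_toy_network <- function(n_mirna = 3, n_lncrna = 3, n_mrna = 4,
                               n_edges = 8) {
  ids <- c(sprintf("m%02d", seq_len(n_mirna)),
           sprintf("l%02d", seq_len(n_lncrna)),
           sprintf("g%02d", seq_len(n_mrna)))
  nodes <- data.frame(
    id = ids,
    class = c(rep("miRNA", n_mirna), rep("lncRNA", n_lncrna),
              rep("mRNA", n_mrna)),
    # direction is a deterministic function of the id so that independent
    # toy networks agree on shared nodes (merge requires consistency)
    direction = ifelse(as.integer(substring(ids, 2)) %% 2 == 0,
                       "up", "down"),
    stringsAsFactors = FALSE)
  pick <- function(cls) sample(nodes$id[nodes$class == cls], 1)
  edges <- list()
  seen <- character(0)
  guard <- 0
  while (length(edges) < n_edges && guard < 1000) {
    guard <- guard + 1
    et <- sample(c("mirna_mrna", "mirna_lncrna", "lncrna_mrna"), 1)
    src_cls <- switch(et, mirna_mrna = "miRNA", mirna_lncrna = "miRNA",
                      lncrna_mrna = "lncRNA")
    tgt_cls <- switch(et, mirna_mrna = "mRNA", mirna_lncrna = "lncRNA",
                      lncrna_mrna = "mRNA")
    s <- pick(src_cls); t <- pick(tgt_cls)
    key <- paste(min(s, t), max(s, t), et)
    if (key %in% seen) next
    seen <- c(seen, key)
    # attributes are a deterministic function of the edge identity, so
    # independently drawn toy networks agree wherever they share an edge
    h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
    edges[[length(edges) + 1]] <- data.frame(
      source = s, target = t, edge_type = et,
      r = round((h %% 199) / 99.5 - 1, 3),
      align_score = if (et == "lncrna_mrna") NA_real_
      else round(100 + (h %% 501) / 10, 1),
      stringsAsFactors = FALSE)
  }
  reg_network(nodes, do.call(rbind, edges))
}

# Canonical comparable form of a reg_network for equality checks.
canonical_network <- function(net) {
  nodes <- net$nodes[order(net$nodes$id), ]
  rownames(nodes) <- NULL
  edges <- net$edges[order(net$edges$source, net$edges$target,
                           net$edges$edge_type), ]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
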