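---
title: "Inferring miRNA-lncRNA-mRNA regulatory networks from count data"
author: "cernanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring miRNA-lncRNA-mRNA regulatory networks from count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Non-coding RNAs shape transcriptional programs in two directions at once:
miRNAs repress mRNAs (and can target lncRNAs), while lncRNAs can act as
competing endogenous RNAs (ceRNAs) that sequester miRNAs and thereby
de-repress the miRNAs' mRNA targets. Studies of complex traits — the
motivating case is ovarian transcriptomes of sheep breeds differing in
fecundity (two high-fecundity Small Tail Han genotypes, distinguished by
the *BMPR1B* FecB allele, against a low-fecundity Dorset control) —
routinely ask which miRNAs, lncRNAs and mRNAs respond to the condition
and how they are wired together.

`cernanet` implements that integrative workflow as a single tested
pipeline over count matrices, sequences and annotations:

1. **Differential expression** per RNA class with an exact
   negative-binomial test;
2. **Target prediction**: seed-match scanning of mRNA 3'UTRs and lncRNAs
   for miRNA binding sites, scored by weighted complementarity;
3. **Correlation pairing**: predicted miRNA targets must be negatively
   correlated with the miRNA; lncRNA-mRNA pairs must be near-perfectly
   correlated;
4. **Network assembly**: the three typed pair networks are merged into a
   tripartite miRNA-lncRNA-mRNA graph with summary statistics and
   Cytoscape-compatible export;
5. **Enrichment**: hypergeometric over-representation of DE/target gene
   sets, plus gene-act / pathway-act networks induced from relation
   tables.

A synthetic-cohort generator with planted regulatory structure makes the
whole pipeline testable end to end against known ground truth.

## Differential expression

### Normalization

Library sizes are removed with median-of-ratios size factors: for sample
$j$, $s_j = \mathrm{median}_f \; k_{fj} / (\prod_{j'} k_{fj'})^{1/m}$,
the median taken over features whose geometric mean across samples is
strictly positive. Features with a zero anywhere drop out of the
reference set only; they are still tested.

### The exact NB test

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. Per feature, the dispersion $\alpha$ is estimated by
method of moments on the normalized counts — pooled within-group variance
$v$, overall normalized mean $q$, $\hat\alpha = (v - q)/q^2$ — floored at
$10^{-8}$. No trend fitting or shrinkage is applied: the exact test is
the load-bearing part of this package and the dispersion stage is kept
deliberately transparent.

The two-group test conditions on the observed total: with group totals of
normalized counts $k_A + k_B = k_S$, the two-sided p-value is the summed
probability of all splits $(a, b)$, $a + b = k_S$, that are no more
probable than the observed split (within a relative tolerance of
$10^{-7}$), normalized by the total probability of the split sum. Group
totals are modelled as sums of $n$ i.i.d. NB$(q, \alpha)$ variables,
which is again negative binomial, NB$(nq,\, n/\alpha)$ — the NB family is
closed under convolution at a common success probability. Working on
normalized totals (rounded to integers) makes the p-values exactly
invariant under rescaling any sample's column together with its size
factor; the test suite asserts this bit-for-bit.

With a single library per group no within-group variance exists; an
explicit `allow_no_replicates` opt-in (with a warning) falls back to a
single "blind" dispersion, the median of per-feature moment estimates
computed with all samples treated as replicates. This mirrors designs
with one library per condition, but it is deliberately not the default:
such designs confound biological variability with the condition effect.

### Calling rules

Two class-specific rules are applied, both with strict inequalities so
boundary values are never called:

* mRNA / lncRNA: up if fold change $> 1.5$ and BH-adjusted $p < 0.05$;
  down if fold change $< 0.667$ and adjusted $p < 0.05$;
* miRNA: up if $\log_2$ fold change $> 1$ and **raw** $p < 0.05$; down
  symmetrically.

The asymmetry (FDR for mRNA/lncRNA, raw p for miRNA) is intentional and
kept behind `de_thresholds()`, where any of the five constants can be
changed. Fold changes use a pseudocount of 0.5 on both normalized group
means so ratios exist at zero counts.

### A calibration caveat, measured

Under a null cohort (2,000 features, 5 samples per group, dispersion
0.05, no planted effects) the raw p-value rate at the 0.05 level runs at
roughly 0.07–0.09 rather than 0.05. The exact test itself is calibrated —
plugging the *true* dispersion into the same machinery gives ~0.043 — so
the inflation is entirely dispersion-estimation noise: with ten samples a
per-feature moments estimate is noisy, and features whose sample variance
fluctuates low hit the $10^{-8}$ floor and look too significant. This is
precisely the weakness that motivated trend-fitted and shrunken
dispersions in later DE methods, which this package intentionally omits.
The test suite measures this property honestly; treat marginal calls at
small replication with corresponding caution, or raise
`dispersion_floor`.

## Target prediction

### Seed sites

The scanner uses the canonical seed taxonomy. Sites are defined on the
target read 5'→3', anchored at exact Watson-Crick complements of the
miRNA seed core (positions 2–7):

| class | definition | span |
|---|---|---|
| 6mer | core complement only | 6 nt |
| 7mer-m8 | core plus pairing of miRNA position 8 | 7 nt |
| 7mer-A1 | core plus an A across from miRNA position 1 | 7 nt |
| 8mer | both | 8 nt |

Each anchor is reported once at its best class; overlapping anchors are
all reported. Coordinates are 0-based, half-open, and cover the
seed-pairing region including the position-1 A where applicable. The same
scanner is applied to mRNA 3'UTRs and to lncRNAs: the package treats
miRNA-lncRNA site prediction identically to miRNA-mRNA prediction.

### Alignment score

Candidate sites are ranked by a miRanda-style complementarity score: a
local alignment (affine gaps) of the miRNA against the reversed site
window (the site extended 30 nt on its 5' target side), with Watson-Crick
match +5, G:U wobble +2, mismatch −3, gap open −8, gap extension −2, and
seed positions 2–8 counted at double weight. Scores are floored at 0. A
perfect 22-nt complement scores $15 \cdot 5 + 7 \cdot 10 = 145$; the
default candidate threshold of 140 is set so that near-perfect
complementarity passes and seed-only matches (around 75) do not. No
thermodynamic term is computed; duplex free energies are out of scope.
Both the scanner and the scorer are verified against independent
exhaustive-window and dynamic-programming oracles in the test suite.

## Correlation rules

All correlations are Pearson coefficients on
$\log_2(\text{normalized count} + 1)$ profiles across the samples of the
comparison; the transform stabilizes variance over the count range.
Profiles need at least 3 observations (r on two points is always ±1);
zero-variance profiles yield an undefined marker and never pair.

* **miRNA-target**: a sequence-predicted candidate is kept as a likely
  true target only when $r < 0$. No magnitude threshold is imposed by
  default — repression evidence is the sign — but `r_max_neg` is
  configurable.
* **lncRNA-mRNA**: pairs require $|r| \ge 0.99$; positive and negative
  pairs are both retained and counted separately. The absolute value is
  used because downstream accounting tabulates both signs.

The requirement of ≥3 samples per group is a deliberate divergence from
single-library-per-condition designs, where a cross-sample Pearson
correlation is not computable; the simulator enforces it.

## Network assembly

Pair tables become typed graphs: nodes carry class (miRNA / lncRNA /
mRNA) and DE direction (up / down); edges carry type (`mirna_mrna`,
`mirna_lncrna`, `lncrna_mrna`), the correlation r, and the alignment
score where applicable. miRNA→target edges are directed from the miRNA;
lncRNA-mRNA co-expression edges are undirected in meaning and stored
with the lncRNA first. Node identity is the raw feature id: the same id
appearing with two classes or directions is an error rather than a
silent merge, which catches id collisions in user data.

`merge_tripartite()` unions the three pair networks; it is commutative,
associative and idempotent, and isolated nodes cannot arise by
construction. `network_stats()` reports node counts per class, edge
counts per type, positive/negative pair counts, degrees, and hubs
defined as nodes at or above a degree quantile (default 0.9) — a
quantile rather than a fixed degree, since "core" nodes are only
meaningful relative to the network at hand. Exports are SIF (with a
fixed edge-type vocabulary), GraphML with full attributes (round-trip
tested), and a node table.

## Enrichment and act-networks

Over-representation uses the hypergeometric upper tail
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$ with a
flat term model (no GO DAG propagation). The background defaults to all
features with nonzero counts in the comparison, since an explicit
universe is rarely recorded. The `enriched` flag uses raw $p < 0.05$, as
is conventional in this literature; BH-adjusted values are always
reported alongside. A hypergeometric test was chosen over alternatives
(e.g. Fisher's exact) as the standard one-sided over-representation
formulation; for this one-sided task they coincide anyway.

Gene-act and pathway-act networks are induced subgraphs of user-supplied
relation tables (STRING-style gene relations typed
`exp/a/b/inh/c/com`; unlabeled pathway-pathway links) on the DE or
enriched entity set, with nodes carrying DE direction for colouring.

## The synthetic cohort

`simulate_cohort()` generates the reference study conditions: three
breed groups (two Han genotypes and a Dorset control) with 5 replicates
each; 500 mRNAs, 50 lncRNAs, 20 miRNAs; NB counts with dispersion 0.05
and baseline means drawn log-uniformly between $2^3$ and $2^8$;
per-sample library size factors log-uniform in $[0.5, 2]$; 10% of
features with a planted 4-fold group effect in a random group and
direction.

Planted structure:

* **miRNA repression.** Each planted miRNA→target edge scales the
  target's group mean by $\rho^{z_g}$, where $z_g$ is the regulator's
  standardized log group mean and $\rho = 0.25$ by default. Repression
  acts on group means, not per sample, so anticorrelation appears across
  groups — the structure a multi-group breed design can actually detect.
  Regulators are drawn from (and if necessary promoted into) the
  planted-DE miRNA set, since only DE miRNAs enter the downstream scan;
  drawing with replacement produces the miRNA-with-many-targets star
  patterns typical of real networks.
* **lncRNA-mRNA co-expression.** Each planted pair shares a per-sample
  latent factor ($2^{\lambda_s}$, $\lambda_s \sim N(0, 2^2)$ on the log2
  scale), with the same loading for positive pairs and opposite loading
  for negative ones; partners also copy (or invert) the lncRNA's group
  effect. At these defaults planted pairs reach $|r| \approx 0.95$ on
  average — deliberately *not* all above the pipeline's 0.99 threshold,
  which is stricter than realistic co-expression noise; the threshold is
  reproduced as given rather than tuned to the simulation.
* **Sequences.** miRNAs are random 22-mers with a 5' U, as canonical
  miRNAs overwhelmingly have. Each planted edge embeds the full reverse
  complement of the regulator at a recorded position in the target; its
  seed-pairing region is exactly the reverse complement of miRNA
  positions 2–8 followed by an A across from position 1, i.e. a
  canonical 8mer site, and the full-length complement scores 145 ≥ 140.
  An isolated 8-nt seed site cannot pass a 140 alignment threshold, so
  planting full complements is the construction under which both the
  scanner and the scoring threshold are exercised meaningfully. Outside
  planted sites, all sequences are iteratively resampled until no
  6mer-or-better match exists for any simulated miRNA, so spurious
  candidates cannot arise from the background.
* **Annotation.** One planted term holds 80% of the planted-DE mRNAs
  plus 10 background genes; the remaining 9 terms are random sets of
  matched size.

Everything is reproducible from `rng_seed` (sequences and annotation use
fixed offsets of it), and the generator returns the full ground truth:
effect matrices, edge lists, site positions.

**What the simulation does not emulate.** GC/length biases, isoform
mixtures, shared miRNA targeting of many genes, overlapping regulatory
programs, batch effects, and count-level outliers are all absent;
sequences are uniform-random rather than genomic. Passing the planted
recovery tests therefore demonstrates the pipeline's internal
correctness — thresholds, wiring, bookkeeping — not predictive accuracy
on real tissue.

## Numerical and design choices

* Exact-test tie comparison uses a relative tolerance of $10^{-7}$
  (probability-mass ordering); p-values are computed in log space.
* Dispersion floor $10^{-8}$; degenerate all-zero features get $p = 1$
  and $\log_2$ fold change 0 via the pseudocount.
* BH adjustment delegates to the standard step-up implementation and is
  verified against a direct computation.
* The pipeline re-estimates size factors and dispersions within each
  two-group comparison, so comparisons are self-contained and
  individually re-runnable.
* No stage caching: at the problem sizes this package targets every
  stage re-runs in seconds, and a content-addressed cache would
  complicate the determinism contract for little gain.
* Test problem sizes: the reference cohort (570 features × 15 samples)
  for end-to-end recovery; 2,000-feature null cohorts over 20 seeds for
  calibration; 100-instance oracle comparisons for the scanner and
  scorer. These sizes were chosen so the full suite documents the
  pipeline's properties at desk scale.

## Known limitations

* Anti-conservative raw p-values at small replication (measured above).
* The |r| ≥ 0.99 lncRNA-mRNA rule is extremely strict for noisy data;
  genuinely co-regulated pairs with realistic noise often fall below it.
* miRNA calls use raw p-values by design fidelity; at thousands of
  candidate miRNAs this admits false positives (the simulation's
  evaluation reports the realized false-discovery proportion).
* Seed classes and the complementarity score are a transparent,
  auditable replacement for black-box target predictors; they do not
  model pairing thermodynamics, conservation, or site context.
* Degree-distribution differences between networks are reported as
  tables only; no significance test is attached, as no standard test
  exists for this comparison.
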