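Package: cernanet
Title: Inference of miRNA-lncRNA-mRNA Regulatory Networks from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for constructing competing-endogenous-RNA
    (ceRNA) regulatory networks from ovarian transcriptome count data across
    breed groups. Implements median-of-ratios normalization and an exact
    negative-binomial two-group test for differential expression with
    class-specific calling thresholds, seed-match prediction of miRNA binding
    sites on mRNA 3'UTRs and lncRNAs with a complementarity alignment score,
    Pearson co-expression pairing rules (high-correlation lncRNA-mRNA pairs,
    negative-correlation miRNA-target filtering), tripartite network assembly
    with Cytoscape-compatible SIF/GraphML export, hypergeometric functional
    enrichment, and gene-act/pathway-act networks from relation tables. A
    synthetic-cohort generator plants differential expression, miRNA-mediated
    repression and lncRNA-mRNA co-expression with known ground truth so the
    whole pipeline can be evaluated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
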