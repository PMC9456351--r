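Package: tfatlas
Title: Gene Gain and Loss Atlases from Gene-Tree/Species-Tree Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers histories of gene family gain (duplication) and loss by
    parsimony reconciliation of gene trees against a time-calibrated species
    tree, with an incomplete-lineage-sorting-aware branch-length threshold
    (N*mu) under which weak gene-tree edges are contracted and re-resolved at
    minimum duplication-loss cost. Aggregates per-family events into a
    per-branch and time-windowed gain/loss-rate atlas, associates gene
    presence/absence with binary life-history traits by a chi-square prescreen
    followed by lasso logistic regression, and tests whether regulator loss
    decelerates molecular evolution of target genes via paired terminal-branch
    rate comparisons. Includes a seeded birth-death gene-family simulator that
    provides ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    knitr,
    rmarkdown
Config/testthat/edition: 3
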