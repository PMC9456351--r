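# tfatlas

Gene gain/loss atlases from gene-tree/species-tree reconciliation, with an
ILS-aware branch-length threshold, trait association and target-gene rate
analysis.

Comparative genomics of gene-family turnover — for example the contraction
of the transcription-factor (TF) repertoire during mammalian radiation —
rests on a chain of inferences: reconcile each ortholog-group (OG) gene tree
against a dated species tree to place duplication (gain) and loss events on
branches; aggregate events into a per-branch, per-My rate atlas; associate
the resulting presence/absence patterns with binary life-history traits; and
ask whether losing a regulator changes the molecular evolutionary rate of
its target genes (TGs). `tfatlas` implements that chain for R users working
with newick trees and TSV tables, and ships a seeded birth–death simulator
that provides ground truth for every stage, so the whole analysis is
testable without genome downloads.

## The core method

For a rooted binary gene tree `G` and dated species tree `S`, the LCA
mapping sends each leaf to its species and each internal node `v` to
`M(v) = lca_S(M(left(v)), M(right(v)))`. Node `v` is a **duplication** iff
`M(c) = M(v)` for a child `c`; each gene edge `(v, c)` implies
`depth(M(c)) − depth(M(v)) − [v is speciation]` **losses**, one on the
off-path child branch of every skipped species node. Under unit costs this
mapping minimizes both the duplication count and the total
duplication+loss cost over all valid embeddings (verified in the tests
against an exhaustive dynamic program). Because every OG is assumed present
as a single copy at the species root, species hanging off the path from the
root to `M(root_G)` contribute stem losses.

Incomplete lineage sorting concentrates discordance on short gene-tree
edges. Per OG the pipeline computes `mu = g · (mean root-to-leaf path) / A`
(substitutions/site/generation; `g` = generation length in years, `A` = root
age in years) and treats internal edges shorter than `T = Ne · mu` as weak:
they are contracted and the resulting polytomies re-resolved at minimum
cost (exhaustive for ≤ 6 children, greedy above, cost never increases).
Sweeping `Ne` over 10^4–10^7 trades discordance absorption against signal.

Downstream: per-branch rates `events / duration(My)` with uniform smearing
for time-windowed rates; a Pearson chi-square prescreen (p < 0.05, no
continuity correction) followed by lasso logistic regression (glmnet,
CV-deviance penalty) of traits on single-copy presence; and a two-sided
paired t test on per-interaction mean terminal-rate differences
(TF-lacking minus TF-retaining species).

## Worked example

```r
library(tfatlas)

s <- parse_newick("((A:1,B:1):1,C:2);", "species")   # ages in My
g <- parse_newick("((A_1,B_1),(A_2,C_1));", "gene")  # leaves: species_copy
rec <- classify_events(g, s, assume_root_origin = FALSE)
rec
#> DL reconciliation: D = 1  L = 2  cost = 3
rec$events
#>   type branch_id species_node
#> 1 loss         B            2
#> 2 gain        N1            4
#> 3 loss         C            3
```

One duplication at the species root explains the two A copies; one copy is
subsequently lost on the B branch and one on the C branch — the parsimony
minimum for this classic discordant quartet.

The full synthetic chain, from simulation to atlas, association and the
TG-rate test:

```r
run <- run_pipeline(default_config(seed = 1), "out/")
```

writes `species_tree.nwk`, per-OG `events.tsv`, the branch `atlas.tsv`,
windowed rates, the trait-association table and the paired-test summary,
plus a manifest with config and checksums; two runs with one seed are
byte-identical. The numbered scripts under `analysis/` run the same stages
with narrative output; on the default conditions (16 taxa, 60 families)
stage 2 prints an Ne sweep in which total inferred events fall
monotonically (216 → 200 → 139 → 95 from Ne = 10^4 to 10^7 against 137
observable true events), and stage 5 recovers the planted TG deceleration
(t = −7.9, p = 1e-4, all pairs below the diagonal).

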