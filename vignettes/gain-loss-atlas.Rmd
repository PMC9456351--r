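---
title: "Reconstructing gene gain/loss histories by reconciliation: models, thresholds and recovery experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene gain/loss histories by reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference chain

`tfatlas` implements a four-stage analysis of gene-family evolution on a
time-calibrated species phylogeny, of the kind used to study the contraction
of the transcription-factor repertoire across mammals:

1. **Reconciliation.** Each ortholog-group (OG) gene tree is embedded into
   the species tree by the LCA mapping: a leaf maps to its species, an
   internal node to the lowest common ancestor of its children's images. A
   node is a *duplication* (gain) when a child maps to the same species
   node; *losses* are read off the species nodes a gene edge skips. Under
   unit event costs this mapping attains the parsimony minimum over all
   valid embeddings, which the test suite verifies against an independent
   dynamic program that enumerates every ancestor-consistent mapping.
2. **Atlas.** Events are summed per species branch and divided by branch
   durations (My) to give gain/loss rates; windowed rates smear each
   branch's events uniformly over its time span.
3. **Trait association.** Species-level presence/absence of single-copy OGs
   is screened against binary life-history traits by a 2x2 Pearson
   chi-square (no continuity correction, p < 0.05) and the survivors enter
   an L1-penalized logistic regression (glmnet), penalty chosen by
   cross-validated deviance. A *negative* presence coefficient means loss of
   the regulator associates with the trait.
4. **Target-gene rates.** For each regulator-target interaction, terminal
   branch lengths of the target-gene tree are converted to rates
   (subs/site/My) using the species tree's terminal durations, averaged
   within the species that retain vs lost the regulator, and the per-pair
   differences (without − with) are tested against zero by a two-sided
   paired t test (Wilcoxon companion reported).

## Assumptions

- The species tree is rooted, binary and ultrametric with node ages in Mya;
  every rate is expressed per My of branch duration, never per unit of
  substitution length.
- Every OG descends from a single copy at the species root (stem-origin
  convention, `assume_root_origin = TRUE`): species hanging off the path
  from the root to the gene root's mapping count as losses. Without this
  convention, loss counts on basal branches are systematically understated.
- Gene-tree discordance is explained only by duplication and loss;
  incomplete lineage sorting (ILS) is not modeled explicitly but absorbed by
  the weak-branch threshold below. Horizontal transfer is out of scope.
- Species are treated as independent observations in the association stage.
  This mirrors the regression design the pipeline reproduces and is *not* a
  phylogenetically corrected test; `associate_trait()` warns on every call.

# The N·mu weak-branch threshold

Short gene-tree branches are where ILS concentrates topological noise. The
pipeline computes, per OG, the substitution rate per generation

  mu_gen = g · (mean root-to-leaf path length) / A,

with `g` the generation length in years (default 10) and `A` the root age in
years. An internal edge shorter than `T = Ne · mu_gen` substitutions/site is
*weak*. Weak edges are contracted into polytomies and every polytomy is
re-resolved into the binary topology of minimum duplication+loss cost.
Terminal edges are never weak: a leaf's species identity is observed data.

Two properties make the local resolution exact and cheap:

- the LCA mapping of a polytomy's node, and the duplication status of its
  parent, are invariant under re-resolution, so the total cost decomposes
  into independent per-polytomy terms;
- each polytomy with k ≤ 6 children is solved by exhaustive enumeration of
  its (2k−3)!! ≤ 945 rooted resolutions; 7–12 children fall back to greedy
  pairwise agglomeration (flagged approximate, with the original topology
  kept as a candidate so the cost never increases); larger polytomies abort
  the OG with a logged reason.

`reconcile_sweep()` runs the Ne grid (10^4, 10^5, 10^6, 10^7) in ascending
order and carries each OG's resolved tree forward as a warm-start candidate.
Because weak-edge sets are nested in Ne, the candidate set at a larger
threshold always contains the smaller threshold's optimum, making total
event counts non-increasing across the grid by construction rather than by
luck.

## Rooting

Unrooted gene trees are rooted by exhaustive search over all edges,
minimizing reconciliation cost. Ties are broken deterministically: prefer
the rooting whose root maps closest to the species root, then the
lexicographically smallest canonical newick. Runs are therefore
reproducible bit for bit.

# The synthetic generator

No genome-scale data ship with the package; every experiment runs on a
seeded generator whose defaults are the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_taxa`, `root_age` | 16, 170 My | desk-scale stand-in for a mammal phylogeny |
| `birth` | 0.025 /My | speciation rate of the conditioned pure-birth tree |
| `dup_rate`, `loss_rate` | 0.0015, 0.003 /lineage/My | a handful of events per family over the tree |
| `rate`, `sigma_r` | 0.002 subs/site/My, 0.3 | relaxed lognormal clock |
| `p_ils`, `eps_len` | 0.2, 0.01 subs/site | fraction and scale of short-edge NNI noise |
| `ne`, `generation_years` | 10^6, 10 | matched threshold T = 0.02 subs/site |
| `delta`, `sigma_g` | 0.3, 0.2 | target-gene deceleration and rate noise |

The species tree is built by a conditioned pure-birth construction: the root
is fixed at age A and the remaining n−2 divergence ages are i.i.d.
truncated-exponential with rate `birth` on (0, A), attached by splitting a
uniformly chosen lineage. This gives the mean-divergence-age closed form
`1/birth − A/(exp(birth·A) − 1)` used as the generator's own oracle in the
tests.

Families descend the species tree as independent birth–death lineages from a
single root copy. The truth tables record **every** event and, separately,
the **observable** events — what a perfect parsimony reconciliation of the
pruned (surviving) tree can recover: duplications with surviving descendants
on *both* sides located at the LCA of their survivors, one loss per maximal
extinct clade placed where the clade began, duplications whose daughters
survive only in disjoint subtrees demoted to speciations. With noise off,
`reconcile_og()` reproduces the observable tables *exactly*, per branch — the
strongest invariant in the test suite.

What the generator does not emulate: sequence-level evolution (lengths are
drawn, not inferred), coalescent ILS (short-edge NNI is a phenomenological
stand-in), gene conversion, and phylogenetic autocorrelation of traits
(traits are i.i.d. Bernoulli given the presence matrix, matching the
non-phylogenetic regression downstream). Passing recovery tests therefore
demonstrate correctness of the inference chain under its own model, not
robustness to every feature of real data.

# Recovery experiments and their design

**ILS threshold** (`ils_threshold_experiment`): 80 families under the study
conditions, 20% of short edges perturbed. False events are the excess of
inferred over observable-truth counts. The matched threshold (Ne = 10^6,
T = g·r = 0.02 subs/site under the generator's clock) removes the large
majority of false events (typically >90%), and the Ne sweep is monotone.

**Spike recovery** (`spike_recovery`): 200 families; the two oldest internal
branches of ≥ 10 My get a planted loss *load* of 0.8 expected events per
crossing lineage over a loss-free background. Two design points matter and
were settled by analysis rather than preference. First, a spike fixed in
events/My is either lethal on a 100-My branch (erasing the very families
that carry the signal — the oldest-branch placement selects root children)
or negligible on a short one; planting an expected load per lineage is
scale-free. Second, per-branch *rates* divide by durations spanning two
orders of magnitude, so with any background loss a single chance event on a
sub-My branch out-ranks a genuine spike on a long branch; the localization
experiment therefore runs background-free, while background-loss regimes
are exercised by the ILS experiment and the exact truth-recovery tests.

**Association recovery** (`association_recovery`): 96 species, 200 columns,
5 causal regulators with |β| = 2, 50 seeds. Causal columns are drawn among
identifiable ones (minority state ≥ 20% of species); a signal planted on a
near-constant column is unrecoverable by construction. Mean recall is ~0.84.
Precision, however, plateaus near 1/3: the chi-square screen is computed on
the full data, so its ~0.05·195 ≈ 10 chance survivors correlate with the
trait inside every cross-validation fold and the lasso retains them at the
CV-chosen penalty (the 1-SE rule changes little). This screening leakage is
inherent to the screen-then-fit design the pipeline reproduces; a
sample-split or screen-free design would avoid it, but would no longer be
the same pipeline. The package reports the measured precision rather than
masking it.

**Paired-test calibration** (`calibrate_paired_test`): groups of 8
regulator-retaining and 4 regulator-lacking species per pair (losses are the
minority in real presence matrices), lognormal rate noise. Type-I error at
α = 0.05 sits within Monte-Carlo error of nominal over 1000 replicates of
500 pairs; power at δ = 0.3, σ_g = 0.2 is ~1. The planted deceleration
always yields mean(without − with) < 0, i.e. scatter points below the
diagonal.

# Numerical choices and degenerate inputs

- Unit event costs (c_dup = c_loss = 1), configurable; parsimony statements
  in the tests all use unit costs.
- Ultrametricity tolerance 1e-6 (relative) when recovering node ages from
  branch lengths; zero-length terminal species branches are rejected.
- A zero-length gene tree yields mu = 0 with a warning (threshold disabled).
- Edges are weak when strictly below T; T = 0 disables rearrangement.
- New internal edges created by polytomy resolution get length 0.
- Duplications mapping to the species root have no subtending branch; the
  atlas collects them in a `root_events` attribute instead of inventing a
  root branch with undefined duration.
- Lasso coefficients are reported on the standardized (per-SD) scale the
  penalty acts on; the intercept is unpenalized. With a single surviving
  column the design matrix is padded with a zero column (glmnet requires
  two) and the pad is stripped from the output.
- Paired tests with all-zero differences return t = 0, p = 1; constant
  nonzero differences return ±Inf with p = 0.

# Problem sizes

The bundled analyses and tests run at 16 taxa, 60–200 families, 50
association seeds and 1000 calibration replicates — sizes chosen so the
complete suite and the reproduction script each finish in well under a
minute on a single core while keeping Monte-Carlo error far from every
asserted bound. All sizes are arguments; nothing in the code depends on
them.

# Known limitations

- Parsimony underestimates event counts when duplication and loss co-occur
  on one branch (the masked-duplication demotion above); the observable
  truth tables quantify exactly what is recoverable.
- The greedy fallback for 7–12-child polytomies is not guaranteed optimal
  (flagged in the output); families with larger polytomies are skipped.
- Rate atlases on sub-My branches are Poisson-noise dominated; windowed and
  epoch-mean views are the intended consumers of the atlas, not single
  short-branch rates.
- The association stage inherits the independence assumption and the
  screening leakage of the design it reproduces; its selected sets are
  candidates, not causal claims.
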