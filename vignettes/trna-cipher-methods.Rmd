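---
title: "Identifying tRNA identity elements outside the anticodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tRNA identity elements outside the anticodon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacipher)
```

## The problem

Aminoacyl-tRNA synthetases (aaRS) charge each tRNA with its cognate amino
acid, and they manage this even when the anticodon is uninformative or
masked. The determinants they rely on — nucleotide identities at positions
outside the anticodon, classically including the discriminator base N73 and
acceptor-stem pairs — are collectively called the *operational RNA code*.
`trnacipher` asks the statistical version of the question: given a large
collection of tRNA gene sequences with known cognate amino acids, which small
set of non-anticodon positions carries enough information to identify the
amino acid, how well does that information generalize across genes, species
and phyla, and does the per-species ensemble of codes track the phylogeny?

The package provides the full pipeline: canonical alignment of tRNA genes,
a classification-tree learner over categorical position states, greedy
forward selection of informative positions (the *moRNA code*, minimal
operational RNA), three cross-validation designs and label-permutation
nulls, per-amino-acid identity-element statistics, species-ensemble
semidistances with complete-linkage dendrograms, and Baker's Gamma
comparison against a reference phylogeny.

## Canonical alignment

tRNA genes are mapped to the classical 76-position cloverleaf numbering
without insertion labels: acceptor stem N1–N7 / N66–N72, discriminator N73,
D domain N8–N26, anticodon stem N27–N33 / N37–N43, anticodon N34–N36,
variable loop N44–N48, TΨC domain N49–N65, and the CCA tail by convention at
N74–N76 (always trimmed, so those slots stay empty). After intron removal
and CCA trimming the anticodon is located — an explicit location wins over a
unique triplet match; anything else is rejected — and the stems fill their
fixed slots from the sequence ends and from the bases adjacent to the
anticodon. Length variation is absorbed at fixed anchors: the D loop
(N14–N21) and T loop (N54–N60) are gapped highest-numbered-slot-first, and
the TΨC arm fills from its 3′ end so that natural variable-loop length
variation lands in N44–N48 rather than corrupting the T stem. Bases beyond a
region's capacity are dropped and counted. Records that cannot be aligned
(out-of-bounds length, missing or ambiguous anticodon, sides shorter than
their stems) never enter the analysis; they go to a reject report.

This fixed-anchor scheme is deliberately simple. It cannot distinguish a
shortened T loop from a shortened variable loop, and it drops rather than
renumbers insertions (no 17a/20a-style labels). For the archaeal-scale
datasets the analysis targets, where most genes are full-length, these cases
are rare and auditable through the reject/dropped bookkeeping.

The default candidate set contains 43 positions: the 15 acceptor-stem
positions (N1–N7, N66–N72, N73) plus the D and TΨC domains minus eight
classically invariant bases (N8, N14, N18, N19, N21, N54, N55, N56). The
anticodon, anticodon stem and variable loop are never candidates. The set is
a configuration item (`run_config()`), not a constant.

## The tree learner

The core model is a CART-style classification tree over categorical
position states, written for exactly this feature type: every feature takes
at most five values (A, C, G, U, gap — the gap is an ordinary fifth
category, since gap presence is itself positional information). Splits are
binary category subsets, scored by information (entropy) gain in bits, with
exhaustive enumeration of the at most 15 binary partitions per position.
Trees are *fully grown*: no pruning, no complexity penalty, no minimum node
size. Growth continues until every leaf is pure or constant on all features;
when no split has positive gain but rows still differ (an XOR-like plateau),
a deterministic zero-gain split is taken so the invariant always holds. A
consequence used throughout the test suite is that resubstitution accuracy
equals, exactly, the best attainable bound — the per-unique-feature-row
majority — which gives an independent oracle for the learner. All
tie-breaks are deterministic (lowest position, then lexicographically
smallest left subset; leaf ties to the alphabetically first class), so fits
are reproducible and order-invariant. Unseen categories at prediction time
route to the child with the larger training count.

The exported `best_split()` keeps the stricter contract of returning nothing
when no split has strictly positive gain; `fit_tree()` documents the
zero-gain fallback it needs to reach full growth.

*Identification accuracy* is one minus the misclassification rate, and the
within-sample (resubstitution) flavor of it is the selection criterion:
`forward_select()` adds, at each step, the position whose refit tree gains
the most cumulative within-sample accuracy (ties to the lowest position
label). Cross-validated accuracy is deliberately *not* the selection
criterion — generalization is measured separately by the validation module,
with selection always repeated inside each training fold.

## Validation designs

Three partitions of the data, mirroring three levels of biological
dependence, plus a permutation null:

* **t-CV** samples tRNA genes (default 2/3 train, 100 replicates).
* **s-CV** samples whole species (default 57 of 86, adjustable), so a
  species' entire gene complement stays on one side.
* **f-CV** trains on one phylum and tests on everything else, both
  directions.
* **permutation null**: labels are permuted uniformly; positions are
  re-selected per replicate on the permuted data; both the resubstitution
  accuracy and a class-stratified 10-fold CV accuracy are averaged (default
  50 permutations). The resubstitution null stays far above the 10-fold null
  because fully grown trees overfit permuted labels — the gap is itself a
  property the tests assert.

Every scheme derives per-replicate RNG substreams from one master seed, so
runs are reproducible and replicate order is irrelevant. Folds for the null
are stratified by class to stabilize a 20-class null at moderate n.

## Per-amino-acid statistics

For one amino acid versus the rest, the marginal value of a single position
is measured by Cramér's V on the nucleotide-state × is-target contingency
(`screen_positions()` produces the full 20 × 43 grid), and a single-position
rule "predict the amino acid iff the state equals x" is summarized by
sensitivity and positive predictive value. The canonical worked example is
histidine: with 86 of 86 His tRNAs carrying C at N73 against 3 of 3850
non-His, the collapsed 2×2 table gives V = 0.98, sensitivity 1.0 and PPV
86/89 ≈ 0.97. Minimal multi-position models (`per_aa_minimal_model()`) run
forward selection on the binary recode until a within-sample accuracy target
(default 99%) is reached, reporting the trivial `X0` baseline (the majority,
non-target share) alongside; `per_aa_f_cv()` trains that minimal model in
one phylum and scores it in the other. No multiple-testing correction is
applied to the screen — these are effect sizes, not hypothesis tests.

## Species ensembles and the moRNA tree

A species' *moRNA ensemble* is its set of (amino acid, code) pairs, where a
code is the string of states at the selected informative positions. The
dissimilarity between two ensembles follows a count–aggregate–average rule:
per shared amino acid, Hamming distances over all cross pairs of codes are
aggregated, and the per-amino-acid values are averaged. The literal
aggregation is the **sum** over cross pairs, and it is the default; note
that under "sum" two *identical* ensembles have distance zero only when
every code set is a singleton (an amino acid with two distinct codes
contributes its internal cross-pair distance). The package flags rather
than hides this: "mean" and "min_match" (optimal bipartite matching, zero
for identical sets) are offered as alternatives. Amino acids present in only
one species are skipped by default, or charged the maximum Hamming distance
under the "penalize" policy. The measure is symmetric and nonnegative but
not a metric — the triangle inequality is not assumed, hence *semidistance*.

Complete-linkage agglomeration (`stats::hclust`) of the semidistance matrix
gives the moRNA tree. Agreement with a reference phylogeny is measured by
Baker's Gamma: the Spearman rank correlation (average ranks on ties) between
the stages at which leaf pairs first co-occur in each tree. Stages are dense
ranks of node heights, where a node's height is the maximum path length down
to its leaves (unit branches when lengths are absent); exact ties share a
rank, so multifurcations count as one stage. For ultrametric dendrograms
this is the usual merge-stage rank; for non-ultrametric references (e.g.
neighbor-joining trees read from Newick) it is a deterministic
generalization. Trees are pruned to their shared leaf set before
comparison. Significance comes from uniformly permuting one tree's leaf
labels (default 1000 times) with the two-sided, +1-corrected p-value
`(1 + #{|γ*| ≥ |γ|}) / (n_perm + 1)`, whose floor at 1000 permutations is
about 0.001. The Robinson–Foulds distance is deliberately not offered: it is
ill-defined for the multifurcating trees complete linkage can produce.

## The synthetic generator

Because the archaeal gene set behind the original analysis has no printed
copy, every claim the package tests is grounded in a generator with full
ground truth (`synth_spec()` / `generate_dataset()`). It emulates the
structure the analysis assumes: two phylum-like clades related by a random
coalescent species tree; 20 amino-acid classes with a few gene copies each
per species; a small set of planted code positions whose states are shared
universally, per phylum (forced to differ between phyla), or drifting along
the tree (each branch mutates a position with probability μ to a uniformly
different state); classically conserved positions with fixed states; and
i.i.d. background everywhere else, with optional site noise ε off the
planted positions, D-loop deletions, and canonically placed introns to
exercise the alignment code.

Default study conditions, chosen once: 30 species in 2 phyla, 2–4 gene
copies per amino acid per species (n ≈ 1800 genes, matching the scale at
which within-sample greedy selection is reliable), eight planted positions
(N1, N2, N3, N11, N22, N51, N70, N73 — acceptor-stem-heavy, like known
identity elements), conserved set equal to the candidate-set exclusions,
μ = 0.1 per branch for drift studies, ε = 0. Root codes are drawn distinct
across amino acids with one deliberate constraint: for each planted position
there is an amino-acid pair whose codes differ *only* there. This makes
every planted position individually necessary — no proper subset of the
planted positions separates all classes — mirroring the premise that
different amino acids rely on different identity positions, and giving
selection-recovery tests a well-defined truth. Without it, a random code
typically becomes separable after ~4 positions and the remaining greedy
steps are unconstrained ties.

What the generator does *not* emulate: post-transcriptional modifications,
secondary-structure constraints between paired stem positions (each position
is generated independently), wobble isoacceptor diversity (one anticodon per
amino acid), codon-usage effects, and realistic D-loop length distributions.
A passing suite therefore shows the pipeline recovers planted structure of
this kind — not that archaeal tRNAs contain it; the latter is an empirical
claim about real data.

Two properties of fully grown trees are worth keeping in mind when reading
results at small n. First, within-sample accuracy includes an overfitting
component: random background columns fragment the unique-row space, so the
resubstitution curve rises even under permuted labels (the permutation null
makes this visible). Second, for the same reason, greedy selection at small
n (a few hundred genes) can prefer a background position's overfit gain to a
planted position's small real gain; at the default study size the real
gains dominate and recovery is exact.

## Reported synthetic studies

`scripts/acceptance.R` recomputes the package's headline quantities on three
seeded studies, all at the default conditions above: a universal-code study
(selection accuracy curve at k = 3/6/8/10, planted-position recall, t-CV and
s-CV means, permutation nulls); an f-CV study with four universal and four
phylum-scoped positions — a fully phylum-swapped code would give a
degenerate near-zero out-of-phylum accuracy, whereas partial conservation is
the structure of interest — and a drift study (μ = 0.1) whose moRNA tree is
compared against the true species tree by Baker's Gamma with 999 label
permutations. The His worked-example statistics are computed from the
printed contingency counts, which are inputs, not outputs.

## Numerical choices and degenerate inputs

* Entropy uses base-2 logs with 0·log 0 = 0; gain comparisons use a 1e-12
  tolerance, so equal-gain ties resolve by the deterministic ordering rather
  than floating-point noise.
* Cramér's V drops zero-margin rows/columns first and errors on tables with
  fewer than two positive rows and columns; constant positions in the
  screens yield `NA` (flagged, never silently zero). Undefined sensitivity
  or PPV is likewise `NA` plus a flag.
* Merge-level ranks treat heights within a relative 1e-8 as tied.
* A Baker's Gamma against a constant merge-level vector (a star tree) is
  `NA`; the permutation test refuses to start from an undefined observed
  value.
* `min_match` aggregation solves the assignment exhaustively over the
  smaller code set (per-amino-acid code sets are tiny) and is capped at 7
  codes.
* Problem sizes in the shipped tests are scaled to the structure being
  verified: oracle equivalences use hundreds of small random tables,
  CV-mechanics tests use reduced candidate sets, and full-recovery tests use
  the default study conditions above.

## Interfaces

All pipeline artifacts are plain text: FASTA with pipe- or key=value-
dialect headers (the scraped metadata behind such datasets has no standard
serialization, so both are documented inventions), Newick trees, TSV
tables, YAML configuration and JSON summaries. `run_pipeline()` orchestrates
the stages and writes a manifest with MD5 checksums; the R functions are the
interface, and each stage can be run or rerun from its upstream artifacts.
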