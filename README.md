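# trnacipher

Identify the cognate amino acid of tRNA genes from nucleotide positions
**outside the anticodon**.

Aminoacyl-tRNA synthetases recognize their tRNAs through identity elements
beyond the anticodon — the *operational RNA code*, classically anchored at
the discriminator base N73 and the acceptor stem. `trnacipher` implements the
statistical side of that question for collections of tRNA gene sequences
(e.g. archaeal tRNAscan-SE predictions): which small set of non-anticodon
positions identifies the amino acid, how well does it generalize across
genes, species and phyla, and does the per-species ensemble of codes track
the phylogeny?

## What it computes

* **Canonical alignment** of tRNA genes onto the classical 76-position
  numbering (CCA trimming, intron removal, fixed-anchor gap insertion), and
  a categorical feature table over a 43-position candidate set (acceptor
  stem + D domain + TΨC domain, minus invariant bases; the anticodon is
  never a feature).
* **Classification trees** over position states: CART-style binary
  category-subset splits by information gain, fully grown (no pruning, no
  size penalty). The within-sample *identification accuracy* is
  1 − misclassification rate.
* **Greedy forward selection** of informative positions: at each step the
  position adding most cumulative within-sample accuracy joins the model.
  The selected set of size *k* (default 8) is the *moRNA code* ("minimal
  operational RNA").
* **Validation**: gene-level (t-CV), species-level (s-CV) and phylum-level
  (f-CV) cross-validation — selection repeated inside every training fold —
  plus label-permutation nulls (resubstitution and stratified 10-fold CV).
* **Per-amino-acid identity elements**: Cramér's V screens
  (amino acid × position), single-position sensitivity/PPV rules, minimal
  one-vs-rest models to a 99% target, and per-amino-acid out-of-phylum
  accuracy.
* **Species ensembles**: per species, the set of (amino acid, moRNA code)
  pairs; a cross-pair Hamming **semidistance** between ensembles;
  complete-linkage moRNA trees; **Baker's Gamma** agreement with a reference
  phylogeny, with a leaf-label permutation test.
* **A synthetic generator** with full ground truth (planted universal /
  phylum-specific / tree-drifting codes) so every stage is testable without
  external data.

## Worked example

The classical identity element is the histidine discriminator base: in a
3936-gene archaeal collection, 86 of 86 His tRNAs carry C at N73, against
3 of 3850 non-His tRNAs.

```r
library(trnacipher)

his <- matrix(c(86, 3, 0, 3847), 2,
              dimnames = list(c("C", "notC"), c("His", "other")))
cramers_v(his)
#> [1] 0.9826185

tab_his <- feature_table(
  matrix(rep(c("C", "C", "G"), c(86, 3, 3847)), dimnames = list(NULL, "N73")),
  rep(c("His", "other", "other"), c(86, 3, 3847)))
st <- single_rule_stats(tab_his, "His", "N73", "C")
c(sensitivity = st$sensitivity, ppv = st$ppv)
#> sensitivity         ppv
#>   1.0000000   0.9662921
```

Cramér's V of 0.98 says this single position nearly perfectly separates His
tRNAs from the rest; the rule "His iff C at N73" catches every His tRNA
(sensitivity 1) and is right 97% of the times it fires (PPV 86/89).

A full synthetic study — generate genes with eight planted code positions,
align, select, cross-validate:

```r
g     <- generate_dataset(synth_spec(seed = 1))   # 30 species, 2 phyla
tab   <- extract_features(prepare_records(g$records))
tab
#> feature_table: 1818 tRNAs x 43 positions, 20 classes

forward_select(tab, 8)
#> forward selection trace:
#>  step position  accuracy
#>     1       N1 0.2145215
#>     2       N2 0.5148515
#>     3       N3 0.7123212
#>     4      N51 0.8085809
#>     5      N11 0.8586359
#>     6      N22 0.9070407
#>     7      N73 0.9537954
#>     8      N70 1.0000000

t_cv(tab, reps = 5, k = 8, seed = 2)
#> t_cv: 5 replicate(s), mean accuracy 1.0000
```

The trace is the cumulative identification accuracy as positions join the
model; here selection recovers exactly the eight planted positions and the
held-out accuracy confirms the code generalizes. `run_pipeline(out_dir)`
runs every stage end to end and writes plain-text artifacts (TSV / JSON /
Newick / FASTA) plus a checksummed manifest.

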