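Package: trnacipher
Title: Identity Elements of tRNA Genes Outside the Anticodon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the cognate amino acid of tRNA genes from nucleotide
    positions outside the anticodon. Provides canonical 76-slot alignment of
    tRNA gene sequences, a categorical classification-tree learner (fully
    grown, information impurity), greedy forward selection of informative
    positions (the "moRNA code"), gene-, species- and phylum-level
    cross-validation with label-permutation nulls, per-amino-acid
    identity-element statistics (Cramer's V, sensitivity, PPV, minimal
    models), species moRNA-ensemble semidistances with complete-linkage
    dendrograms, and Baker's Gamma comparison of dendrograms against a
    reference phylogeny with a leaf-permutation test. Includes a synthetic
    tRNA-gene generator with full ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
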