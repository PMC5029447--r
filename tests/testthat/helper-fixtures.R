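# shared fixtures and independent oracles

# feature table from an explicit character matrix
toy_table <- function(x, labels, species = NULL, phylum = NULL) {
  if (is.null(colnames(x))) colnames(x) <- paste0("N", seq_len(ncol(x)))
  feature_table(x, labels, species, phylum)
}

# random categorical table over a subset of the RNA alphabet
random_table <- function(n, p, ncat = 4, nclass = 3) {
  x <- matrix(sample(c("A", "C", "G", "U", "-")[seq_len(ncat)], n * p,
                     replace = TRUE),
              nrow = n, dimnames = list(NULL, paste0("N", seq_len(p))))
  labels <- sample(LETTERS[seq_len(nclass)], n, replace = TRUE)
  list(x = x, labels = labels)
}

# oracle: best attainable resubstitution accuracy of any classifier on the
# features = majority class per unique feature row
unique_row_majority_bound <- function(x, labels) {
  key <- apply(x, 1, paste, collapse = "\r")
  sum(vapply(split(labels, key), function(l) max(table(l)), 0)) / nrow(x)
}

# oracle: exhaustive search over all (position, binary category subset)
# splits; returns the maximal information gain and all argmax splits
brute_force_splits <- function(x, labels) {
  h <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  parent <- table(labels)
  hp <- h(parent)
  n <- nrow(x)
  best_gain <- -Inf
  argmax <- list()
  for (j in seq_len(ncol(x))) {
    cats <- sort(unique(x[, j]))
    if (length(cats) < 2) next
    for (m in seq_len(2^length(cats) - 2)) {
      inl <- as.logical(bitwAnd(m, 2^(seq_along(cats) - 1)))
      if (!inl[1]) next  # canonical side
      left <- x[, j] %in% cats[inl]
      gain <- hp - (sum(left) / n) * h(table(labels[left])) -
        (sum(!left) / n) * h(table(labels[!left]))
      if (gain > best_gain + 1e-9) {
        best_gain <- gain
        argmax <- list(list(position = colnames(x)[j], left = cats[inl]))
      } else if (abs(gain - best_gain) <= 1e-9) {
        argmax <- c(argmax, list(list(position = colnames(x)[j],
                                      left = cats[inl])))
      }
    }
  }
  list(gain = best_gain, argmax = argmax)
}

# oracle: resubstitution accuracy of the best tree on a fixed position
# subset equals the unique-row majority bound on those columns
subset_accuracy <- function(tab, positions, labels = tab$labels) {
  unique_row_majority_bound(tab$x[, positions, drop = FALSE], labels)
}

# exhaustive best subsets of size k by the subset_accuracy criterion
exhaustive_best_subsets <- function(tab, k, labels = tab$labels) {
  combs <- utils::combn(tab$positions, k, simplify = FALSE)
  acc <- vapply(combs, function(ps) subset_accuracy(tab, ps, labels), 0)
  best <- max(acc)
  list(accuracy = best,
       subsets = lapply(combs[abs(acc - best) <= 1e-12],
                        function(ps) sort(ps)))
}

# a small deterministic FASTA fixture on disk
write_toy_fasta <- function(path, headers, seqs) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# 73-nt gene body laid out exactly on canonical slots N1..N73 (no gaps),
# with a given anticodon at N34-N36; deterministic filler elsewhere
identity_body <- function(anticodon = "GUG") {
  slots <- rep(c("G", "C", "U", "A"), length.out = 73)
  slots[34:36] <- strsplit(anticodon, "")[[1]]
  paste(slots, collapse = "")
}
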