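# internal alphabet: RNA letters plus the alignment gap, in this fixed order
# (the order defines the category coding used by the tree learner and the
# lexicographic tie-break on split subsets)
RNA_ALPHABET <- c("A", "C", "G", "U", "-")

# the 20 canonical amino acids, 3-letter codes, alphabetical
AMINO_ACIDS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val")

# canonical position labels N1..N76; N34-N36 are the anticodon
ANTICODON_SLOTS <- c("N34", "N35", "N36")

pos_label <- function(i) paste0("N", i)

pos_num <- function(label) {
  n <- suppressWarnings(as.integer(sub("^N", "", label)))
  if (anyNA(n)) stop("malformed position label(s): ",
                     paste(label[is.na(n)], collapse = ", "))
  n
}

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and maps T to U. Idempotent. Characters outside
#' `{A,C,G,U,T,-}` (case-insensitive) are an error.
#'
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,U,-}`.
#' @export
normalize_rna <- function(x) {
  out <- chartr("acgut", "ACGUU", x)
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGU-]", out)
  if (any(bad)) stop("non-nucleotide characters in sequence(s): ",
                     paste(which(bad), collapse = ", "))
  out
}

# integer-code a character matrix over the RNA alphabet for the C++ learner
code_states <- function(x) {
  m <- match(x, RNA_ALPHABET)
  if (anyNA(m)) stop("states outside {A,C,G,U,-} in feature matrix")
  matrix(m - 1L, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
}

# deterministic per-replicate substreams from one master seed
replicate_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
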