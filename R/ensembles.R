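#' Build species moRNA ensembles
#'
#' Per species and amino acid, the deduplicated set of code strings (states
#' at the moRNA positions, fixed order). Also emits a census: the number of
#' unique codes overall and per amino acid, and the number of species
#' carrying each (amino acid, code) pair.
#'
#' @param tab a [feature_table()] with species metadata.
#' @param morna_positions the moRNA position labels, in order.
#' @return object of class `morna_ensembles`: `ensembles` (named list,
#'   species -> named list amino acid -> character vector of codes),
#'   `positions`, `census` (list: `n_unique_codes`, `per_aa` named vector,
#'   `code_species` data frame `amino_acid`, `code`, `n_species`).
#' @export
build_ensembles <- function(tab, morna_positions) {
  if (any(is.na(tab$species)))
    stop("feature table has rows without a species")
  codes <- extract_morna_codes(tab, morna_positions)
  df <- data.frame(species = tab$species, amino_acid = tab$labels,
                   code = codes, stringsAsFactors = FALSE)
  df <- unique(df)
  ens <- lapply(split(df, df$species), function(d)
    lapply(split(d$code, d$amino_acid), sort))
  pair <- unique(df[, c("amino_acid", "code")])
  n_sp <- vapply(seq_len(nrow(pair)), function(i)
    sum(df$amino_acid == pair$amino_acid[i] & df$code == pair$code[i]), 0L)
  census <- list(
    n_unique_codes = nrow(pair),
    per_aa = vapply(split(pair$code, pair$amino_acid), length, 0L),
    code_species = data.frame(pair, n_species = n_sp,
                              stringsAsFactors = FALSE))
  structure(list(ensembles = ens, positions = morna_positions,
                 census = census),
            class = "morna_ensembles")
}

#' @export
print.morna_ensembles <- function(x, ...) {
  cat(sprintf("morna_ensembles: %d species, %d positions, %d unique codes\n",
              length(x$ensembles), length(x$positions),
              x$census$n_unique_codes))
  invisible(x)
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

cross_hamming <- function(codes1, codes2) {
  outer(codes1, codes2, Vectorize(hamming))
}

# optimal bipartite matching cost by exhaustive assignment over the smaller
# side (code sets per amino acid are tiny); cost = sum over matched pairs
min_match_cost <- function(h) {
  if (nrow(h) > ncol(h)) h <- t(h)
  k <- nrow(h)
  if (k > 7) stop("min_match aggregation capped at 7 codes per amino acid")
  if (k == 0) return(0)
  perms <- all_permutations(ncol(h), k)
  min(vapply(seq_len(nrow(perms)), function(i)
    sum(h[cbind(seq_len(k), perms[i, ])]), 0))
}

all_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  sub <- all_permutations(n, k - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(j) {
    keep <- !apply(sub == j, 1, any)
    cbind(sub[keep, , drop = FALSE], j)
  }))
  out
}

#' Semidistance between two species moRNA ensembles
#'
#' Per amino acid shared by both species, the Hamming distances between all
#' cross pairs of code strings from the two code sets are aggregated:
#' `"sum"` adds them (the literal rule; note it is positive for identical
#' ensembles when an amino acid carries two or more distinct codes), `"mean"`
#' averages them, `"min_match"` takes the optimal bipartite matching cost.
#' The per-amino-acid values are then averaged. Amino acids present in only
#' one species are skipped (`missing_aa_policy = "skip"`) or contribute the
#' maximum Hamming distance (`"penalize"`); amino acids in neither are always
#' excluded.
#'
#' @param e1,e2 per-species code lists (named list amino acid -> character
#'   vector), e.g. elements of `build_ensembles()$ensembles`. Code strings
#'   must all share one length (the moRNA size).
#' @param aggregation `"sum"` (default), `"mean"` or `"min_match"`.
#' @param missing_aa_policy `"skip"` (default) or `"penalize"`.
#' @return a nonnegative number; symmetric in `e1`, `e2`.
#' @export
ensemble_semidistance <- function(e1, e2,
                                  aggregation = c("sum", "mean", "min_match"),
                                  missing_aa_policy = c("skip", "penalize")) {
  aggregation <- match.arg(aggregation)
  missing_aa_policy <- match.arg(missing_aa_policy)
  lens <- nchar(unlist(c(e1, e2)))
  if (length(unique(lens)) > 1)
    stop("code strings of differing lengths: the two ensembles must use the ",
         "same moRNA position set")
  width <- lens[1]
  shared <- intersect(names(e1), names(e2))
  only <- union(setdiff(names(e1), names(e2)), setdiff(names(e2), names(e1)))
  per_aa <- vapply(shared, function(aa) {
    h <- cross_hamming(e1[[aa]], e2[[aa]])
    switch(aggregation,
           sum = sum(h),
           mean = mean(h),
           min_match = min_match_cost(h))
  }, 0)
  if (missing_aa_policy == "penalize" && length(only))
    per_aa <- c(per_aa, rep(width, length(only)))
  if (length(per_aa) == 0) return(0)
  mean(per_aa)
}

#' All-pairs ensemble semidistance matrix
#'
#' @param ensembles a `morna_ensembles` object.
#' @inheritParams ensemble_semidistance
#' @return symmetric species x species matrix with zero diagonal.
#' @export
distance_matrix <- function(ensembles, aggregation = "sum",
                            missing_aa_policy = "skip") {
  ens <- ensembles$ensembles
  sp <- names(ens)
  k <- length(sp)
  d <- matrix(0, k, k, dimnames = list(sp, sp))
  if (k < 2) return(d)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- ensemble_semidistance(
        ens[[i]], ens[[j]], aggregation, missing_aa_policy)
    }
  }
  stopifnot(all(d >= 0), all(diag(d) == 0), isTRUE(all.equal(d, t(d))))
  d
}

#' Complete-linkage dendrogram from a semidistance matrix
#'
#' Agglomerative clustering merging, at each stage, the pair of clusters with
#' the smallest maximum inter-point dissimilarity ([stats::hclust()] with
#' `method = "complete"`).
#'
#' @param d symmetric nonnegative matrix with zero diagonal (e.g. from
#'   [distance_matrix()]), or a [stats::dist] object.
#' @return an [stats::hclust] dendrogram.
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (any(m < 0)) stop("distance matrix has negative entries")
    d <- as.dist(m)
  } else if (any(d < 0)) {
    stop("distance matrix has negative entries")
  }
  hclust(d, method = "complete")
}
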