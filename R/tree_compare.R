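# dense rank with a relative tolerance, ties share a rank
dense_rank_tol <- function(v, tol = NULL) {
  tol <- tol %||% (1e-8 * max(1, max(abs(v))))
  o <- order(v)
  grp <- cumsum(c(1, diff(v[o]) > tol))
  out <- integer(length(v))
  out[o] <- grp
  out
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "hclust")) return(ape::as.phylo(tree))
  if (inherits(tree, "phylo")) return(tree)
  stop("tree must be an 'hclust' or 'phylo' object")
}

#' Merge-level matrix of a dendrogram
#'
#' Internal nodes are ranked by height (the maximum path length from the node
#' down to any of its leaves; unit branch lengths when the tree carries
#' none), with exact ties sharing a rank — so multifurcations, and tied
#' binary merges, count as one stage. Entry `(i, j)` is the rank of the
#' lowest common ancestor of leaves `i` and `j`: the stage at which the two
#' leaves first co-occur in one cluster. For an ultrametric dendrogram this
#' is the usual merge-stage rank.
#'
#' @param tree an [stats::hclust] dendrogram or rooted [ape::phylo] tree with
#'   at least 2 leaves.
#' @return symmetric integer matrix with leaf-label dimnames; diagonal 0 by
#'   convention; off-diagonal entries in `[1, number of stages]`.
#' @export
merge_levels <- function(tree) {
  tr <- as_phylo_tree(tree)
  ntip <- ape::Ntip(tr)
  if (ntip < 2) stop("merge levels need at least 2 leaves")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  depth <- ape::node.depth.edgelength(tr)  # distance from the root
  nnode <- ntip + tr$Nnode
  maxleaf <- rep(-Inf, nnode)
  maxleaf[seq_len(ntip)] <- depth[seq_len(ntip)]
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    maxleaf[par] <- max(maxleaf[par], maxleaf[ch])
  }
  height <- maxleaf - depth  # subtree height per node
  inodes <- (ntip + 1):nnode
  rank <- integer(nnode)
  rank[inodes] <- dense_rank_tol(height[inodes])
  anc <- ape::mrca(tr)
  ml <- matrix(rank[anc], ntip, ntip,
               dimnames = list(tr$tip.label, tr$tip.label))
  diag(ml) <- 0L
  ml
}

# align two trees on their shared leaves and return the two merge-level
# matrices in one label order
aligned_merge_levels <- function(t1, t2) {
  p1 <- as_phylo_tree(t1)
  p2 <- as_phylo_tree(t2)
  shared <- intersect(p1$tip.label, p2$tip.label)
  if (length(shared) < 3)
    stop("need at least 3 shared leaves, found ", length(shared))
  if (length(shared) < ape::Ntip(p1)) p1 <- ape::keep.tip(p1, shared)
  if (length(shared) < ape::Ntip(p2)) p2 <- ape::keep.tip(p2, shared)
  m1 <- merge_levels(p1)[shared, shared]
  m2 <- merge_levels(p2)[shared, shared]
  list(m1 = m1, m2 = m2, shared = shared)
}

gamma_from_matrices <- function(m1, m2) {
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  if (length(unique(v1)) < 2 || length(unique(v2)) < 2) return(NA_real_)
  cor(v1, v2, method = "spearman")
}

#' Baker's Gamma agreement between two trees
#'
#' Spearman rank correlation (average ranks on ties) between the merge-level
#' vectors of the two trees over all pairs of shared leaves. The trees are
#' pruned to their shared leaf set first. A tree compared with itself (or
#' with any monotone height transform of itself) gives 1; a constant
#' merge-level vector (e.g. a star tree) has undefined correlation and yields
#' `NA`.
#'
#' @param t1,t2 [stats::hclust] or rooted [ape::phylo] trees sharing at least
#'   3 leaves.
#' @return a number in `[-1, 1]`, or `NA` when undefined.
#' @export
bakers_gamma <- function(t1, t2) {
  al <- aligned_merge_levels(t1, t2)
  gamma_from_matrices(al$m1, al$m2)
}

#' Leaf-label permutation test for Baker's Gamma
#'
#' Per replicate the leaf labels of `t1` are permuted uniformly and the gamma
#' against `t2` is recomputed; the two-sided p-value is
#' `(1 + #\{|gamma_perm| >= |gamma_obs|\}) / (n_perm + 1)`, so its floor is
#' `1 / (n_perm + 1)`.
#'
#' @inheritParams bakers_gamma
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @param quantiles null quantiles to report.
#' @return list with `gamma`, `p_value`, `null_quantiles`, `null` (the
#'   permuted gammas).
#' @export
gamma_permutation_test <- function(t1, t2, n_perm = 1000, seed = 1,
                                   quantiles = c(0.025, 0.975, 0.005, 0.995)) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  al <- aligned_merge_levels(t1, t2)
  obs <- gamma_from_matrices(al$m1, al$m2)
  if (is.na(obs)) stop("observed gamma is undefined (constant merge levels)")
  n <- length(al$shared)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    gamma_from_matrices(al$m1[p, p], al$m2)
  }, 0)
  p_value <- (1 + sum(abs(null) >= abs(obs), na.rm = TRUE)) / (n_perm + 1)
  list(gamma = obs, p_value = p_value,
       null_quantiles = quantile(null, quantiles, na.rm = TRUE),
       null = null)
}

ladder_order <- function(tree) {
  tr <- ape::ladderize(as_phylo_tree(tree))
  tr <- ape::reorder.phylo(tr, "cladewise")
  e2 <- tr$edge[, 2]
  tr$tip.label[e2[e2 <= ape::Ntip(tr)]]
}

#' Tanglegram leaf pairing of two trees
#'
#' Leaf orders come from each tree's deterministic ladderized layout; shared
#' leaves are paired with their position in each order (the data behind a
#' tanglegram, without the drawing).
#'
#' @inheritParams bakers_gamma
#' @return data frame `leaf`, `pos1`, `pos2`, one row per shared leaf.
#' @export
tanglegram_pairing <- function(t1, t2) {
  o1 <- ladder_order(t1)
  o2 <- ladder_order(t2)
  shared <- intersect(o1, o2)
  data.frame(leaf = shared, pos1 = match(shared, o1),
             pos2 = match(shared, o2), stringsAsFactors = FALSE)
}
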