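new_cv_result <- function(scheme, accuracies, selected, seed) {
  structure(list(scheme = scheme, accuracies = accuracies,
                 mean_accuracy = mean(accuracies), selected = selected,
                 rng_seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: %d replicate(s), mean accuracy %.4f\n", x$scheme,
              length(x$accuracies), x$mean_accuracy))
  invisible(x)
}

# one CV replicate: select k positions on the training rows only, fit the
# tree on those positions, score on the held-out rows
cv_replicate <- function(tab, labels, train_idx, k) {
  test_idx <- setdiff(seq_along(labels), train_idx)
  tr_tab <- subset_rows(tab, train_idx)
  sel <- forward_select(tr_tab, k, labels = labels[train_idx])$selected
  model <- fit_tree(tr_tab$x[, sel, drop = FALSE], labels[train_idx])
  pred <- predict(model, tab$x[test_idx, , drop = FALSE])
  list(accuracy = identification_accuracy(labels[test_idx], pred),
       selected = sel)
}

#' tRNA-level cross-validation (t-CV)
#'
#' Per replicate: sample a training fraction of the tRNA genes without
#' replacement, run forward selection of `k` positions on the training rows
#' only, fit the tree on those positions, and score identification accuracy
#' on the held-out genes.
#'
#' @param tab a [feature_table()].
#' @param frac training fraction (default 2/3).
#' @param reps replicates (default 100).
#' @param k number of selected positions (default 8).
#' @param seed master seed; replicate substreams are derived from it.
#' @param labels class labels (default: the table's own).
#' @return a `cv_result`.
#' @export
t_cv <- function(tab, frac = 2 / 3, reps = 100, k = 8, seed = 1,
                 labels = NULL) {
  labels <- labels %||% tab$labels
  n <- length(labels)
  n_train <- floor(n * frac)
  if (n_train < 1) stop("training fraction leaves no training rows")
  if (k > length(tab$positions)) stop("k exceeds the candidate count")
  seeds <- replicate_seeds(seed, reps)
  acc <- numeric(reps)
  sel <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    train_idx <- sample.int(n, n_train)
    rep_out <- cv_replicate(tab, labels, train_idx, k)
    acc[r] <- rep_out$accuracy
    sel[[r]] <- rep_out$selected
  }
  new_cv_result("t_cv", acc, sel, seed)
}

#' Species-level cross-validation (s-CV)
#'
#' Like [t_cv()] but entire species are sampled into the training set, so all
#' tRNAs of a species fall on one side of the partition.
#'
#' @param n_train_species species count in the training set.
#' @inheritParams t_cv
#' @return a `cv_result`.
#' @export
s_cv <- function(tab, n_train_species = 57, reps = 100, k = 8, seed = 1,
                 labels = NULL) {
  labels <- labels %||% tab$labels
  species <- tab$species
  all_sp <- unique(species)
  if (length(all_sp) < 2) stop("need at least 2 species")
  if (n_train_species >= length(all_sp))
    stop("n_train_species must be below the total species count")
  seeds <- replicate_seeds(seed, reps)
  acc <- numeric(reps)
  sel <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    train_sp <- sample(all_sp, n_train_species)
    train_idx <- which(species %in% train_sp)
    rep_out <- cv_replicate(tab, labels, train_idx, k)
    acc[r] <- rep_out$accuracy
    sel[[r]] <- rep_out$selected
  }
  new_cv_result("s_cv", acc, sel, seed)
}

#' Phylum-level cross-validation (f-CV)
#'
#' Trains on all tRNAs of one phylum (selection included) and scores on all
#' remaining tRNAs; optionally both directions.
#'
#' @param tab a [feature_table()] with a phylum column.
#' @param train_phylum phylum name, or a vector of names (one accuracy per
#'   direction; the default uses every phylum present in turn).
#' @param k number of selected positions.
#' @param labels class labels (default: the table's own).
#' @return a `cv_result` with one replicate per direction; `selected` holds
#'   the per-direction position sets, named by training phylum.
#' @export
f_cv <- function(tab, train_phylum = NULL, k = 8, labels = NULL) {
  labels <- labels %||% tab$labels
  phyla <- unique(tab$phylum[!is.na(tab$phylum)])
  if (length(phyla) < 2) stop("need at least 2 phyla")
  train_phylum <- train_phylum %||% phyla
  unknown <- setdiff(train_phylum, phyla)
  if (length(unknown)) stop("unknown training phylum: ",
                            paste(unknown, collapse = ", "))
  acc <- numeric(length(train_phylum))
  sel <- vector("list", length(train_phylum))
  names(sel) <- train_phylum
  for (i in seq_along(train_phylum)) {
    train_idx <- which(tab$phylum == train_phylum[i])
    if (length(train_idx) == 0 || length(train_idx) == length(labels))
      stop("phylum split leaves an empty train or test side")
    rep_out <- cv_replicate(tab, labels, train_idx, k)
    acc[i] <- rep_out$accuracy
    sel[[i]] <- rep_out$selected
  }
  res <- new_cv_result("f_cv", acc, sel, NA_integer_)
  names(res$accuracies) <- train_phylum
  res
}

# stratified fold assignment: within each class, shuffled rows get folds
# cyclically, so every fold sees every class whenever the class has >= folds
# members
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Label-permutation null accuracies
#'
#' Per replicate the class labels are permuted uniformly, `k` positions are
#' re-selected on the permuted data, and two statistics are computed: the
#' resubstitution accuracy of the refit tree, and the stratified 10-fold CV
#' accuracy of trees fitted on the same `k` positions within the folds. Both
#' are averaged over replicates. The resubstitution null stays far above the
#' CV null because fully grown trees overfit permuted labels.
#'
#' @param tab a [feature_table()] with at least 10 rows.
#' @param n_perm permutation replicates (default 50).
#' @param k number of selected positions.
#' @param folds CV folds (default 10).
#' @param seed master seed.
#' @param labels class labels (default: the table's own).
#' @return list with `mean_resub`, `mean_cv`, and the per-replicate data
#'   frame `replicates`.
#' @export
permutation_null <- function(tab, n_perm = 50, k = 8, folds = 10, seed = 1,
                             labels = NULL) {
  labels <- labels %||% tab$labels
  n <- length(labels)
  if (n < 10) stop("need at least 10 rows")
  if (n_perm < 1) stop("n_perm must be positive")
  seeds <- replicate_seeds(seed, n_perm)
  resub <- numeric(n_perm)
  cvacc <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    set.seed(seeds[r])
    y <- sample(labels)
    sel <- forward_select(tab, k, labels = y)$selected
    resub[r] <- fit_tree(tab$x[, sel, drop = FALSE], y)$resub_accuracy
    fold <- stratified_folds(y, folds)
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      if (length(te) == 0 || length(tr) == 0) next
      m <- fit_tree(tab$x[tr, sel, drop = FALSE], y[tr])
      correct <- correct + sum(predict(m, tab$x[te, , drop = FALSE]) == y[te])
    }
    cvacc[r] <- correct / n
  }
  list(mean_resub = mean(resub), mean_cv = mean(cvacc),
       replicates = data.frame(perm = seq_len(n_perm), resub = resub,
                               cv = cvacc))
}
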