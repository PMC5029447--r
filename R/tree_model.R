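#' Shannon entropy of class counts, in bits
#'
#' @param class_counts nonnegative counts, not all zero.
#' @return `-sum(p * log2(p))` with `0 * log(0) = 0`.
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be nonnegative")
  n <- sum(class_counts)
  if (n == 0) stop("all-zero counts")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

# integer-code a character feature matrix and label vector for the backend
code_problem <- function(x, labels) {
  classes <- sort(unique(as.character(labels)))
  list(X = code_states(x),
       y = match(as.character(labels), classes) - 1L,
       classes = classes)
}

mask_to_cats <- function(mask) RNA_ALPHABET[bitwAnd(mask, 2L^(0:4)) > 0]

#' Best single binary split of a categorical feature table
#'
#' Scans every position and every binary partition of its observed categories
#' and returns the split maximizing information gain. Ties break by lowest
#' position (column) order, then by the lexicographically smallest left
#' subset. Returns `NULL` when no split has strictly positive gain (in
#' particular when all rows are identical on all features).
#'
#' @param x character feature matrix (columns = position labels).
#' @param labels per-row class labels.
#' @return `NULL`, or `list(position, left_categories, gain)`.
#' @export
best_split <- function(x, labels) {
  stopifnot(nrow(x) >= 2)
  cp <- code_problem(x, labels)
  s <- cart_best_split_cpp(cp$X, cp$y, length(cp$classes))
  if (s$col < 1 || s$gain <= 1e-12) return(NULL)
  list(position = colnames(x)[s$col],
       left_categories = mask_to_cats(s$mask),
       gain = s$gain)
}

#' Fit a fully grown classification tree on categorical position features
#'
#' CART-style recursive binary partitioning with the information (entropy)
#' impurity, no size penalty, no pruning and no minimum node size: growth
#' continues until every leaf is pure or its rows are identical on all
#' features. Zero-gain splits are taken when needed to reach that state, so
#' the tree's resubstitution accuracy always equals the per-unique-feature-row
#' majority bound. All tie-breaks are deterministic (lowest position order,
#' then lexicographically smallest left subset; leaf majorities tie to the
#' alphabetically first class).
#'
#' @param x character feature matrix over `{A,C,G,U,-}` with position-label
#'   colnames, or a [feature_table()].
#' @param labels per-row class labels (ignored when `x` is a feature table,
#'   unless supplied).
#' @return an object of class `cart_tree`.
#' @export
fit_tree <- function(x, labels = NULL) {
  if (inherits(x, "feature_table")) {
    labels <- labels %||% x$labels
    x <- x$x
  }
  if (is.null(dim(x)) || nrow(x) == 0) stop("empty feature table")
  stopifnot(length(labels) == nrow(x))
  cp <- code_problem(x, labels)
  fit <- cart_fit_cpp(cp$X, cp$y, length(cp$classes))
  structure(list(nodes = fit, classes = cp$classes,
                 positions = colnames(x),
                 resub_accuracy = fit$resub_accuracy),
            class = "cart_tree")
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf(
    "cart_tree: %d nodes (%d leaves), %d classes, %d positions, resub accuracy %.4f\n",
    length(x$nodes$split_col), sum(x$nodes$split_col < 0),
    length(x$classes), length(x$positions), x$resub_accuracy))
  invisible(x)
}

#' Predict class labels from a fitted tree
#'
#' Rows are routed down the tree; a category unseen at a node during training
#' is routed to the child with the larger training count (ties to the left
#' child).
#'
#' @param object a `cart_tree`.
#' @param newdata character feature matrix or [feature_table()] containing
#'   the model's positions (matched by column name).
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$x
  miss <- setdiff(object$positions, colnames(newdata))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(newdata) == 0) return(character(0))
  X <- code_states(newdata[, object$positions, drop = FALSE])
  nd <- object$nodes
  p <- cart_predict_cpp(nd$split_col, nd$route_mask, nd$left, nd$right,
                        nd$pred, X)
  object$classes[p + 1L]
}

#' Identification accuracy
#'
#' One minus the misclassification rate: the fraction of exact matches
#' between true and predicted labels.
#'
#' @param true_labels,predicted_labels equal-length nonempty vectors.
#' @return a number in `[0, 1]`.
#' @export
identification_accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("length mismatch between true and predicted labels")
  if (length(true_labels) == 0) stop("empty label vectors")
  mean(as.character(true_labels) == as.character(predicted_labels))
}

#' Serialize a tree to a human-readable rule list
#'
#' Each leaf becomes one rule: the conjunction of the split conditions on the
#' path from the root, the predicted class, and the leaf's class counts.
#'
#' @param model a `cart_tree`.
#' @return data frame with columns `rule`, `class`, `n`.
#' @export
tree_rules <- function(model) {
  nd <- model$nodes
  out_rule <- character(0)
  out_class <- character(0)
  out_n <- integer(0)
  walk <- function(node, conds) {
    i <- node + 1L
    if (nd$split_col[i] < 0) {
      out_rule <<- c(out_rule, if (length(conds)) paste(conds, collapse = " & ")
                               else "TRUE")
      out_class <<- c(out_class, model$classes[nd$pred[i] + 1L])
      out_n <<- c(out_n, nd$n[i])
      return(invisible())
    }
    pos <- model$positions[nd$split_col[i] + 1L]
    lc <- mask_to_cats(nd$left_mask[i])
    walk(nd$left[i], c(conds, sprintf("%s in {%s}", pos,
                                      paste(lc, collapse = ","))))
    walk(nd$right[i], c(conds, sprintf("%s not in {%s}", pos,
                                       paste(lc, collapse = ","))))
  }
  walk(0L, character(0))
  data.frame(rule = out_rule, class = out_class, n = out_n,
             stringsAsFactors = FALSE)
}
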