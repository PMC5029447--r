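#' Greedy forward selection of informative positions
#'
#' At each step, every remaining candidate position is appended to the
#' current set, a fully grown tree is fitted, and the position yielding the
#' highest within-sample (resubstitution) identification accuracy is kept.
#' Ties break to the lowest position label (numeric order). The cumulative
#' accuracy curve is non-decreasing because fully grown trees attain the
#' per-unique-row majority bound, which can only grow as columns are added.
#'
#' @param tab a [feature_table()].
#' @param k_max number of positions to select (`0` gives an empty trace).
#' @param labels class labels (default: the table's own). Supplying e.g. a
#'   binary recode runs selection on that target instead.
#' @param stop_accuracy optional early stop: selection halts at the first
#'   step whose accuracy reaches this value.
#' @return object of class `selection_trace`: data frame `steps` (`step`,
#'   `position`, `accuracy`), plus `selected` (character vector).
#' @export
forward_select <- function(tab, k_max, labels = NULL, stop_accuracy = NULL) {
  stopifnot(inherits(tab, "feature_table"))
  labels <- labels %||% tab$labels
  if (nrow(tab$x) == 0) stop("empty feature table")
  if (k_max > length(tab$positions))
    stop("k_max exceeds the number of candidate positions")
  candidates <- tab$positions[order(pos_num(tab$positions))]
  selected <- character(0)
  acc <- numeric(0)
  k_max <- as.integer(k_max)
  while (length(selected) < k_max) {
    best_acc <- -1
    best_pos <- NA_character_
    for (pos in setdiff(candidates, selected)) {
      a <- fit_tree(tab$x[, c(selected, pos), drop = FALSE],
                    labels)$resub_accuracy
      if (a > best_acc + 1e-12) {
        best_acc <- a
        best_pos <- pos
      }
    }
    selected <- c(selected, best_pos)
    acc <- c(acc, best_acc)
    if (!is.null(stop_accuracy) && best_acc >= stop_accuracy) break
  }
  structure(list(steps = data.frame(step = seq_along(selected),
                                    position = selected, accuracy = acc,
                                    stringsAsFactors = FALSE),
                 selected = selected),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("forward selection trace:\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Prefix of the selected positions
#'
#' @param trace a `selection_trace`.
#' @param k prefix length (default: full trace).
#' @return character vector of the first `k` selected positions.
#' @export
selected_positions <- function(trace, k = nrow(trace$steps)) {
  if (k > nrow(trace$steps)) stop("k exceeds the trace length")
  trace$selected[seq_len(k)]
}

#' Extract per-tRNA moRNA code strings
#'
#' Concatenates each row's states at the given positions, in the given
#' order. Deduplication is left to downstream consumers.
#'
#' @param tab a [feature_table()].
#' @param positions position labels, a subset of the table's candidate set.
#' @return character vector, one code per row (`""` for an empty set).
#' @export
extract_morna_codes <- function(tab, positions) {
  if (length(positions) == 0) return(rep("", nrow(tab$x)))
  miss <- setdiff(positions, tab$positions)
  if (length(miss)) stop("unknown position label(s): ",
                         paste(miss, collapse = ", "))
  apply(tab$x[, positions, drop = FALSE], 1L, paste, collapse = "")
}

#' Pairwise position-position association (Cramer's V)
#'
#' For every pair of candidate positions, Cramer's V on their nucleotide
#' state contingency table. Constant positions have undefined association and
#' yield `NA` (flagged, not an error). Watson-Crick paired stem positions
#' show up as entries near 1.
#'
#' @param tab a [feature_table()] with at least 2 rows.
#' @return symmetric `p x p` matrix, unit diagonal, entries in `[0, 1]` or
#'   `NA`.
#' @export
position_association <- function(tab) {
  stopifnot(inherits(tab, "feature_table"), nrow(tab$x) >= 2)
  p <- length(tab$positions)
  v <- matrix(NA_real_, p, p, dimnames = list(tab$positions, tab$positions))
  varying <- apply(tab$x, 2L, function(col) length(unique(col)) > 1)
  for (i in seq_len(p)) {
    if (varying[i]) v[i, i] <- 1
    if (i == p) next
    for (j in (i + 1L):p) {
      if (!varying[i] || !varying[j]) next
      tt <- table(tab$x[, i], tab$x[, j])
      v[i, j] <- v[j, i] <- cramers_v(tt)
    }
  }
  v
}
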