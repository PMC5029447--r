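#' Cramer's V for a contingency table
#'
#' `sqrt(chisq / (n * (min(r, c) - 1)))` with the Pearson chi-square
#' statistic, no continuity correction. Rows or columns with zero marginals
#' are dropped first; fewer than two positive rows and columns is an error
#' (degenerate marginals).
#'
#' @param tab a matrix (or `table`) of nonnegative counts.
#' @return a number in `[0, 1]`.
#' @export
cramers_v <- function(tab) {
  m <- as.matrix(unclass(tab))
  if (any(m < 0)) stop("counts must be nonnegative")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("degenerate marginals: need >= 2 rows and columns with positive counts")
  chi2 <- suppressWarnings(
    unname(chisq.test(m, correct = FALSE)$statistic))
  v2 <- chi2 / (sum(m) * (min(dim(m)) - 1))
  sqrt(max(0, min(1, v2)))
}

#' One-vs-rest single-position rule statistics
#'
#' The rule "predict `amino_acid` iff the state at `position` equals
#' `nucleotide`", scored on the 2x2 confusion counts: sensitivity
#' `TP / (TP + FN)` and positive predictive value `TP / (TP + FP)`, plus the
#' Cramer's V of the collapsed 2x2 (state == nucleotide) x (label ==
#' amino_acid) table. When `nucleotide` is missing, the state maximizing the
#' sensitivity-PPV product is used (ties to the alphabetically first state).
#' Undefined ratios are returned as `NA` and flagged in `undefined`.
#'
#' @param tab a [feature_table()].
#' @param amino_acid target class label (must be present).
#' @param position position label.
#' @param nucleotide optional state in `{A,C,G,U,-}`.
#' @return list of class `single_position_stat` with `amino_acid`, `position`,
#'   `nucleotide`, `cramers_v`, `sensitivity`, `ppv`, `counts` (named TP, FP,
#'   FN, TN), `undefined`.
#' @export
single_rule_stats <- function(tab, amino_acid, position, nucleotide = NULL) {
  if (!amino_acid %in% tab$labels)
    stop("amino acid '", amino_acid, "' absent from the labels")
  if (!position %in% tab$positions)
    stop("unknown position label: ", position)
  states <- tab$x[, position]
  is_target <- tab$labels == amino_acid
  if (is.null(nucleotide)) {
    cand <- intersect(RNA_ALPHABET, unique(states))  # alphabet order
    prod_best <- -1
    for (nt in cand) {
      st <- rule_counts(states, is_target, nt)
      pr <- (st["TP"] / (st["TP"] + st["FN"])) *
        (st["TP"] / max(1, st["TP"] + st["FP"]))
      if (is.finite(pr) && pr > prod_best) {
        prod_best <- pr
        nucleotide <- nt
      }
    }
  } else if (!nucleotide %in% states) {
    stop("nucleotide '", nucleotide, "' never observed at ", position)
  }
  cnt <- rule_counts(states, is_target, nucleotide)
  sens <- if (cnt["TP"] + cnt["FN"] > 0) cnt["TP"] / (cnt["TP"] + cnt["FN"])
          else NA_real_
  ppv <- if (cnt["TP"] + cnt["FP"] > 0) cnt["TP"] / (cnt["TP"] + cnt["FP"])
         else NA_real_
  cc <- matrix(c(cnt["TP"], cnt["FN"], cnt["FP"], cnt["TN"]), 2, 2)
  v <- tryCatch(cramers_v(cc), error = function(e) NA_real_)
  structure(list(amino_acid = amino_acid, position = position,
                 nucleotide = nucleotide, cramers_v = v,
                 sensitivity = unname(sens), ppv = unname(ppv),
                 counts = cnt, undefined = is.na(sens) || is.na(ppv)),
            class = "single_position_stat")
}

rule_counts <- function(states, is_target, nucleotide) {
  hit <- states == nucleotide
  c(TP = sum(hit & is_target), FP = sum(hit & !is_target),
    FN = sum(!hit & is_target), TN = sum(!hit & !is_target))
}

#' Screen every (amino acid, position) pair by Cramer's V
#'
#' For each class and each candidate position, Cramer's V of the full
#' nucleotide-state x (is-target) contingency (up to 5 x 2). Constant
#' positions yield `NA`.
#'
#' @param tab a [feature_table()].
#' @param amino_acids classes to screen (default: all present, sorted).
#' @return numeric matrix, amino acids x positions.
#' @export
screen_positions <- function(tab, amino_acids = NULL) {
  amino_acids <- amino_acids %||% sort(unique(tab$labels))
  p <- length(tab$positions)
  out <- matrix(NA_real_, length(amino_acids), p,
                dimnames = list(amino_acids, tab$positions))
  for (j in seq_len(p)) {
    states <- tab$x[, j]
    if (length(unique(states)) < 2) next  # constant column: V undefined
    for (aa in amino_acids) {
      tt <- table(states, factor(tab$labels == aa, levels = c(FALSE, TRUE)))
      out[aa, j] <- tryCatch(cramers_v(tt), error = function(e) NA_real_)
    }
  }
  out
}

#' Minimal one-vs-rest position model for one amino acid
#'
#' Forward selection on the binary recode (`amino_acid` vs rest), stopping at
#' the first step whose within-sample accuracy reaches `target_accuracy`. The
#' baseline `x0` is the frequency of the majority (non-target) class, i.e.
#' the accuracy of predicting "rest" everywhere.
#'
#' @param tab a [feature_table()].
#' @param amino_acid target class.
#' @param target_accuracy within-sample accuracy to reach (default 0.99).
#'   `0` returns an empty model (the `x0` baseline already meets it).
#' @param k_max cap on the model size (default: all positions).
#' @return list with `amino_acid`, `positions`, `curve` (data frame `step`,
#'   `position`, `accuracy`), `x0`, `k`, `met` (logical: target reached).
#' @export
per_aa_minimal_model <- function(tab, amino_acid, target_accuracy = 0.99,
                                 k_max = length(tab$positions)) {
  if (!amino_acid %in% tab$labels)
    stop("amino acid '", amino_acid, "' absent from the labels")
  y <- ifelse(tab$labels == amino_acid, amino_acid, "rest")
  x0 <- mean(y == "rest")
  if (target_accuracy <= x0 || k_max == 0) {
    return(list(amino_acid = amino_acid, positions = character(0),
                curve = data.frame(step = integer(0), position = character(0),
                                   accuracy = numeric(0)),
                x0 = x0, k = 0L, met = target_accuracy <= x0))
  }
  tr <- forward_select(tab, k_max, labels = y,
                       stop_accuracy = target_accuracy)
  met <- any(tr$steps$accuracy >= target_accuracy)
  k <- if (met) which(tr$steps$accuracy >= target_accuracy)[1] else
    nrow(tr$steps)
  list(amino_acid = amino_acid, positions = tr$selected[seq_len(k)],
       curve = tr$steps, x0 = x0, k = as.integer(k), met = met)
}

#' Per-amino-acid out-of-phylum accuracy (per-AA f-CV)
#'
#' For each direction: the minimal one-vs-rest model is selected and fitted on
#' the tRNAs of one phylum, then scored on the tRNAs of the other phylum. The
#' two directional accuracies and their average are reported.
#'
#' @param tab a [feature_table()] with exactly two phyla represented.
#' @param amino_acid target class; must be present in both phyla.
#' @param target_accuracy within-sample target for the minimal model.
#' @return list with `directions` (data frame `train_phylum`, `test_phylum`,
#'   `k`, `accuracy`) and `mean_accuracy`.
#' @export
per_aa_f_cv <- function(tab, amino_acid, target_accuracy = 0.99) {
  phyla <- unique(tab$phylum[!is.na(tab$phylum)])
  if (length(phyla) != 2) stop("need exactly 2 phyla")
  for (ph in phyla)
    if (!amino_acid %in% tab$labels[tab$phylum == ph])
      stop("amino acid '", amino_acid, "' absent from phylum ", ph)
  acc <- numeric(2)
  kk <- integer(2)
  for (i in 1:2) {
    tr_idx <- which(tab$phylum == phyla[i])
    te_idx <- which(tab$phylum == phyla[3 - i])
    tr_tab <- subset_rows(tab, tr_idx)
    mm <- per_aa_minimal_model(tr_tab, amino_acid, target_accuracy)
    y_te <- ifelse(tab$labels[te_idx] == amino_acid, amino_acid, "rest")
    if (mm$k == 0L) {
      pred <- rep("rest", length(te_idx))
    } else {
      y_tr <- ifelse(tr_tab$labels == amino_acid, amino_acid, "rest")
      model <- fit_tree(tr_tab$x[, mm$positions, drop = FALSE], y_tr)
      pred <- predict(model, tab$x[te_idx, , drop = FALSE])
    }
    acc[i] <- identification_accuracy(y_te, pred)
    kk[i] <- mm$k
  }
  list(directions = data.frame(train_phylum = phyla,
                               test_phylum = rev(phyla), k = kk,
                               accuracy = acc, stringsAsFactors = FALSE),
       mean_accuracy = mean(acc))
}
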