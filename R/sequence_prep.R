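# Canonical numbering used throughout: the classical 76-position scheme,
# without insertion labels (no 17a/20a/e-positions). Region layout:
#   N1-N7    acceptor stem, 5' side
#   N8-N26   D domain (stems + D loop; gaps inserted in the loop)
#   N27-N33  anticodon stem, 5' side
#   N34-N36  anticodon
#   N37-N43  anticodon stem, 3' side
#   N44-N48  variable loop
#   N49-N65  TPsiC domain (gaps inserted in the T loop)
#   N66-N72  acceptor stem, 3' side
#   N73      discriminator base
#   N74-N76  CCA tail by convention; always gaps after trimming

ACCEPTOR5 <- 1:7
D_REGION <- 8:26
AC_STEM5 <- 27:33
ANTICODON <- 34:36
AC_STEM3 <- 37:43
VAR_LOOP <- 44:48
T_REGION <- 49:65
ACCEPTOR3 <- 66:73

# classically invariant bases, excluded from the default candidate set
DEFAULT_CONSERVED_EXCLUSIONS <- c("N8", "N14", "N18", "N19", "N21",
                                  "N54", "N55", "N56")

#' Default candidate position set
#'
#' Acceptor stem (N1-N7, N66-N72) plus the discriminator base N73, the D
#' domain (N8-N26) and the TPsiC domain (N49-N65), minus a conserved-base
#' exclusion list; 43 labels with the default exclusions. The anticodon,
#' anticodon stem and variable loop are never candidates.
#'
#' @param conserved_exclusions position labels to drop.
#' @return character vector of position labels, in ascending position order.
#' @export
default_candidate_positions <- function(
    conserved_exclusions = DEFAULT_CONSERVED_EXCLUSIONS) {
  pos <- sort(c(ACCEPTOR5, ACCEPTOR3, D_REGION, T_REGION))
  setdiff(pos_label(pos), conserved_exclusions)
}

#' Strip a trailing CCA tail
#'
#' Removes one trailing `CCA` if present (exactly once); otherwise returns
#' the sequence unchanged.
#'
#' @param sequence normalized sequence string.
#' @return list with `sequence` and logical `trimmed`.
#' @export
strip_cca <- function(sequence) {
  if (endsWith(sequence, "CCA")) {
    list(sequence = substr(sequence, 1L, nchar(sequence) - 3L), trimmed = TRUE)
  } else {
    list(sequence = sequence, trimmed = FALSE)
  }
}

#' Remove intron spans from a sequence
#'
#' @param sequence sequence string.
#' @param intron_spans two-column matrix of 0-based half-open `[start, end)`
#'   spans, or `NULL`.
#' @return the concatenation of the inter-span segments, order preserved.
#' @export
remove_introns <- function(sequence, intron_spans = NULL) {
  if (is.null(intron_spans) || NROW(intron_spans) == 0) return(sequence)
  sp <- as.matrix(intron_spans)
  if (ncol(sp) != 2L) stop("intron spans must be a 2-column matrix")
  n <- nchar(sequence)
  if (any(sp[, 1] < 0) || any(sp[, 2] > n) || any(sp[, 2] <= sp[, 1]))
    stop("intron span out of range")
  sp <- sp[order(sp[, 1]), , drop = FALSE]
  if (nrow(sp) > 1 && any(sp[-1, 1] < sp[-nrow(sp), 2]))
    stop("overlapping intron spans")
  keep_start <- c(0L, sp[, 2])
  keep_end <- c(sp[, 1], n)
  segs <- substring(sequence, keep_start + 1L, keep_end)
  paste(segs, collapse = "")
}

# Fill a slot region with `bases`: gaps go to the highest-numbered slots of
# the loop window first (then, if still short, to the highest-numbered
# remaining slots of the region); surplus bases beyond the region capacity
# are dropped from the 3' end and counted.
place_region <- function(bases, region, loop_window = region) {
  n_slot <- length(region)
  dropped <- 0L
  if (length(bases) > n_slot) {
    dropped <- length(bases) - n_slot
    bases <- bases[seq_len(n_slot)]
  }
  g <- n_slot - length(bases)
  gap_order <- c(sort(intersect(loop_window, region), decreasing = TRUE),
                 sort(setdiff(region, loop_window), decreasing = TRUE))
  gap_slots <- gap_order[seq_len(g)]
  out <- rep("-", n_slot)
  names(out) <- pos_label(region)
  fill <- sort(setdiff(region, gap_slots))
  if (length(fill)) out[pos_label(fill)] <- bases
  list(slots = out, dropped = dropped)
}

#' Map one tRNA gene onto the canonical 76-slot numbering
#'
#' Expects a CCA-stripped, intron-free, normalized sequence. The anticodon is
#' placed at N34-N36 (located by `anticodon_start` when given, otherwise by a
#' unique match of the anticodon triplet); the stems fill their fixed slots
#' from the sequence ends and from the bases adjacent to the anticodon; the
#' remaining bases fill the D and TPsiC regions, gapped inside the loops
#' (highest-numbered loop slots first). Variable-loop or D-region bases
#' beyond capacity are dropped and counted.
#'
#' @param sequence CCA-stripped, intron-free sequence.
#' @param anticodon 3-base anticodon.
#' @param anticodon_start optional 0-based index of the anticodon in
#'   `sequence`.
#' @param len_bounds admissible post-trim sequence length range.
#' @return on success `list(ok = TRUE, slots = <named length-76 vector>,
#'   dropped = <int>)`; on rejection `list(ok = FALSE, reason = <text>)`.
#' @export
align_to_canonical <- function(sequence, anticodon, anticodon_start = NA,
                               len_bounds = c(60L, 100L)) {
  e <- nchar(sequence)
  if (e < len_bounds[1] || e > len_bounds[2])
    return(list(ok = FALSE, reason = sprintf(
      "sequence length %d outside bounds [%d, %d]", e, len_bounds[1],
      len_bounds[2])))
  if (!is.na(anticodon_start)) {
    p <- as.integer(anticodon_start) + 1L  # 1-based first anticodon base
    if (p < 1L || p + 2L > e ||
        substr(sequence, p, p + 2L) != anticodon)
      return(list(ok = FALSE, reason = "anticodon_start does not match anticodon"))
  } else {
    hits <- gregexpr(anticodon, sequence, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) == 0)
      return(list(ok = FALSE, reason = "anticodon not found"))
    if (length(hits) > 1)
      return(list(ok = FALSE, reason = "ambiguous anticodon"))
    p <- hits[1]
  }
  n5 <- p - 1L           # bases 5' of the anticodon
  n3 <- e - (p + 2L)     # bases 3' of the anticodon
  if (n5 < 14L)
    return(list(ok = FALSE, reason = "5' side shorter than its stem slots"))
  if (n3 < 15L)
    return(list(ok = FALSE, reason = "3' side shorter than its stem slots"))

  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  slots <- rep("-", 76L)
  names(slots) <- pos_label(1:76)
  slots[pos_label(ACCEPTOR5)] <- ch[1:7]
  slots[pos_label(AC_STEM5)] <- ch[(p - 7L):(p - 1L)]
  slots[pos_label(ANTICODON)] <- ch[p:(p + 2L)]
  slots[pos_label(AC_STEM3)] <- ch[(p + 3L):(p + 9L)]
  slots[pos_label(ACCEPTOR3)] <- ch[(e - 7L):e]

  dropped <- 0L
  d_bases <- if (n5 > 14L) ch[8:(p - 8L)] else character(0)
  d <- place_region(d_bases, D_REGION, loop_window = 14:21)
  slots[names(d$slots)] <- d$slots
  dropped <- dropped + d$dropped

  mid <- if (e - 8L >= p + 10L) ch[(p + 10L):(e - 8L)] else character(0)
  m <- length(mid)
  n_t <- min(m, 17L)                     # TPsiC arm fills from its 3' end
  t_bases <- if (n_t > 0) mid[(m - n_t + 1L):m] else character(0)
  v_bases <- if (m > 17L) mid[seq_len(m - 17L)] else character(0)
  tt <- place_region(t_bases, T_REGION, loop_window = 54:60)
  slots[names(tt$slots)] <- tt$slots
  vv <- place_region(v_bases, VAR_LOOP)
  slots[names(vv$slots)] <- vv$slots
  dropped <- dropped + tt$dropped + vv$dropped

  list(ok = TRUE, slots = slots, dropped = dropped)
}

#' Align a batch of tRNA gene records
#'
#' Runs intron removal, CCA trimming and [align_to_canonical()] on every
#' record. Rejected records never enter the slot matrix; they are returned in
#' a reject report with the reason.
#'
#' @param records a `trna_records` data frame.
#' @param len_bounds admissible post-trim sequence length range.
#' @return list of class `aligned_trna_set`: `slots` (character matrix,
#'   records x 76 canonical positions), `meta` (metadata rows of the retained
#'   records), `rejects` (data frame `record_id`, `reason`).
#' @export
prepare_records <- function(records, len_bounds = c(60L, 100L)) {
  n <- nrow(records)
  slots <- matrix("-", nrow = 0, ncol = 76,
                  dimnames = list(NULL, pos_label(1:76)))
  keep <- logical(n)
  rows <- vector("list", n)
  rej_id <- character(0)
  rej_reason <- character(0)
  for (i in seq_len(n)) {
    s <- remove_introns(records$sequence[i], records$intron_spans[[i]])
    s <- strip_cca(s)$sequence
    a <- align_to_canonical(s, records$anticodon[i],
                            records$anticodon_start[i], len_bounds)
    if (a$ok) {
      keep[i] <- TRUE
      rows[[i]] <- a$slots
    } else {
      rej_id <- c(rej_id, records$record_id[i])
      rej_reason <- c(rej_reason, a$reason)
    }
  }
  if (any(keep))
    slots <- do.call(rbind, rows[keep])
  rownames(slots) <- records$record_id[keep]
  meta <- as.data.frame(records)[keep, c("record_id", "species_id", "phylum",
                                         "amino_acid", "anticodon")]
  rownames(meta) <- NULL
  structure(list(slots = slots, meta = meta,
                 rejects = data.frame(record_id = rej_id, reason = rej_reason,
                                      stringsAsFactors = FALSE)),
            class = "aligned_trna_set")
}

#' Feature table of nucleotide states at candidate positions
#'
#' @param x character matrix over `{A,C,G,U,-}`, columns named by position
#'   labels.
#' @param labels per-row class label (amino acid).
#' @param species,phylum optional per-row metadata.
#' @return list of class `feature_table` with elements `x`, `positions`,
#'   `labels`, `species`, `phylum`.
#' @export
feature_table <- function(x, labels, species = NULL, phylum = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (is.null(colnames(x))) stop("feature matrix needs position-label colnames")
  if (any(colnames(x) %in% ANTICODON_SLOTS))
    stop("candidate positions must exclude the anticodon (N34-N36)")
  if (any(!x %in% RNA_ALPHABET)) stop("states outside {A,C,G,U,-}")
  structure(list(x = x, positions = colnames(x),
                 labels = as.character(labels),
                 species = if (is.null(species)) rep(NA_character_, nrow(x))
                           else as.character(species),
                 phylum = if (is.null(phylum)) rep(NA_character_, nrow(x))
                          else as.character(phylum)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d tRNAs x %d positions, %d classes\n",
              nrow(x$x), length(x$positions), length(unique(x$labels))))
  invisible(x)
}

# row subset helper shared by the CV schemes
subset_rows <- function(tab, idx) {
  feature_table(tab$x[idx, , drop = FALSE], tab$labels[idx],
                tab$species[idx], tab$phylum[idx])
}

# column subset helper (selection steps)
subset_positions <- function(tab, positions) {
  miss <- setdiff(positions, tab$positions)
  if (length(miss)) stop("unknown position label(s): ",
                         paste(miss, collapse = ", "))
  feature_table(tab$x[, positions, drop = FALSE], tab$labels,
                tab$species, tab$phylum)
}

#' Extract the candidate-position feature table from aligned tRNAs
#'
#' @param aligned an `aligned_trna_set` from [prepare_records()].
#' @param candidate_positions ordered position labels (default the
#'   43-position set).
#' @return a [feature_table()] labeled by amino acid.
#' @export
extract_features <- function(aligned,
                             candidate_positions = default_candidate_positions()) {
  if (any(candidate_positions %in% ANTICODON_SLOTS))
    stop("candidate positions must exclude the anticodon (N34-N36)")
  miss <- setdiff(candidate_positions, colnames(aligned$slots))
  if (length(miss)) stop("unknown position label(s): ",
                         paste(miss, collapse = ", "))
  feature_table(aligned$slots[, candidate_positions, drop = FALSE],
                aligned$meta$amino_acid, aligned$meta$species_id,
                aligned$meta$phylum)
}
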