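#' tRNA gene records
#'
#' A `trna_records` object is a data frame with one row per tRNA gene and
#' columns `record_id`, `species_id`, `phylum`, `amino_acid`, `anticodon`,
#' `sequence`, `anticodon_start` (0-based index of the anticodon's first base
#' in the intron-free sequence, `NA` when unknown) and `intron_spans` (a list
#' column of two-column matrices of 0-based half-open `[start, end)`
#' coordinates on the raw sequence, `NULL` when none).
#'
#' @param record_id,species_id,phylum,amino_acid,anticodon,sequence
#'   character vectors, recycled to a common length.
#' @param anticodon_start optional integer vector (0-based), `NA` allowed.
#' @param intron_spans optional list of two-column matrices (or `NULL`s).
#' @return a data frame of class `trna_records`.
#' @export
trna_records <- function(record_id, species_id, phylum = NA_character_,
                         amino_acid, anticodon, sequence,
                         anticodon_start = NA_integer_,
                         intron_spans = NULL) {
  n <- length(record_id)
  df <- data.frame(record_id = record_id,
                   species_id = species_id,
                   phylum = rep_len(as.character(phylum), n),
                   amino_acid = amino_acid,
                   anticodon = normalize_rna(anticodon),
                   sequence = normalize_rna(sequence),
                   anticodon_start = rep_len(as.integer(anticodon_start), n),
                   stringsAsFactors = FALSE)
  if (is.null(intron_spans)) intron_spans <- vector("list", n)
  df$intron_spans <- intron_spans
  validate_trna_records(df)
  class(df) <- c("trna_records", "data.frame")
  df
}

KNOWN_AA <- c(AMINO_ACIDS, "iMet", "Und")

validate_trna_records <- function(df) {
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id: ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "))
  bad_aa <- !(df$amino_acid %in% KNOWN_AA)
  if (any(bad_aa))
    stop("unrecognized amino-acid code in record(s): ",
         paste(df$record_id[bad_aa], collapse = ", "))
  if (any(!nzchar(df$sequence)))
    stop("empty sequence in record(s): ",
         paste(df$record_id[!nzchar(df$sequence)], collapse = ", "))
  if (any(nchar(df$anticodon) != 3L))
    stop("anticodon must be 3 bases")
  for (i in seq_len(nrow(df))) {
    sp <- df$intron_spans[[i]]
    if (is.null(sp)) next
    sp <- as.matrix(sp)
    if (ncol(sp) != 2L) stop("intron spans must be 2-column")
    if (any(sp[, 1] < 0) || any(sp[, 2] > nchar(df$sequence[i])) ||
        any(sp[, 2] <= sp[, 1]))
      stop("intron span out of range in record ", df$record_id[i])
    o <- order(sp[, 1])
    if (nrow(sp) > 1 && any(sp[o, 1][-1] < sp[o, 2][-nrow(sp)]))
      stop("overlapping intron spans in record ", df$record_id[i])
    # check declared anticodon against its declared location
    }
  has_start <- !is.na(df$anticodon_start)
  if (any(has_start)) {
    for (i in which(has_start)) {
      s <- remove_introns(df$sequence[i], df$intron_spans[[i]])
      trip <- substr(s, df$anticodon_start[i] + 1L, df$anticodon_start[i] + 3L)
      if (trip != df$anticodon[i])
        stop("anticodon_start of record ", df$record_id[i],
             " does not point at the declared anticodon (found '", trip, "')")
    }
  }
  invisible(df)
}

format_span_token <- function(sp) {
  if (is.null(sp) || nrow(sp) == 0) return("")
  paste(sprintf("%d-%d", sp[, 1], sp[, 2]), collapse = ";")
}

parse_span_token <- function(tok) {
  if (is.na(tok) || !nzchar(tok)) return(NULL)
  parts <- strsplit(strsplit(tok, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
  colnames(m) <- c("start", "end")
  m
}

#' Read tRNA gene records from FASTA
#'
#' Headers carry the metadata in one of two dialects. The `"pipe"` dialect is
#' `record_id|species|phylum|amino_acid|anticodon` (phylum may be empty). The
#' `"keyvalue"` dialect is space-separated `key=value` tokens with mandatory
#' keys `id`, `species`, `aa`, `anticodon`, optional `phylum`,
#' `anticodon_start` (0-based) and `introns` (`start-end;start-end`, 0-based
#' half-open). Sequences are normalized to RNA letters (T mapped to U).
#'
#' @param path FASTA file.
#' @param header_dialect `"pipe"` or `"keyvalue"`.
#' @param imet_to_met merge initiator-Met records into `Met` (default TRUE).
#' @param drop_noncanonical drop records whose amino-acid code is not one of
#'   the 20 canonical codes after the iMet merge (default FALSE).
#' @return a `trna_records` data frame (zero rows for an empty file).
#' @export
read_trna_fasta <- function(path, header_dialect = c("pipe", "keyvalue"),
                            imet_to_met = TRUE, drop_noncanonical = FALSE) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 ||
      !any(startsWith(readLines(path, warn = FALSE), ">")))
    return(empty_records())
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           whole.header = TRUE)
  headers <- vapply(fa, function(s) attr(s, "Annot"), "")
  headers <- sub("^>", "", headers)
  seqs <- toupper(vapply(fa, as.character, ""))

  if (header_dialect == "pipe") {
    toks <- strsplit(headers, "|", fixed = TRUE)
    need <- vapply(toks, length, 0L) < 5L
    if (any(need))
      stop("pipe header needs 5 fields (id|species|phylum|aa|anticodon); ",
           "offending record(s): ",
           paste(vapply(toks[need], `[`, "", 1), collapse = ", "))
    meta <- data.frame(record_id = vapply(toks, `[`, "", 1),
                       species_id = vapply(toks, `[`, "", 2),
                       phylum = vapply(toks, `[`, "", 3),
                       amino_acid = vapply(toks, `[`, "", 4),
                       anticodon = vapply(toks, `[`, "", 5),
                       stringsAsFactors = FALSE)
    meta$anticodon_start <- NA_integer_
    spans <- vector("list", nrow(meta))
  } else {
    kv <- lapply(strsplit(headers, "[[:space:]]+"), function(tk) {
      tk <- tk[nzchar(tk)]
      eq <- regexpr("=", tk, fixed = TRUE)
      stats::setNames(substring(tk, eq + 1L), substring(tk, 1L, eq - 1L))
    })
    get <- function(x, key) if (key %in% names(x)) x[[key]] else NA_character_
    meta <- data.frame(
      record_id = vapply(kv, get, "", key = "id"),
      species_id = vapply(kv, get, "", key = "species"),
      phylum = vapply(kv, get, "", key = "phylum"),
      amino_acid = vapply(kv, get, "", key = "aa"),
      anticodon = vapply(kv, get, "", key = "anticodon"),
      stringsAsFactors = FALSE)
    meta$anticodon_start <-
      as.integer(vapply(kv, get, "", key = "anticodon_start"))
    spans <- lapply(vapply(kv, get, "", key = "introns"), parse_span_token)
  }
  miss <- is.na(meta$amino_acid) | !nzchar(meta$amino_acid) |
    is.na(meta$species_id) | !nzchar(meta$species_id)
  if (any(miss))
    stop("missing amino-acid or species field in record(s): ",
         paste(ifelse(nzchar(meta$record_id[miss]) & !is.na(meta$record_id[miss]),
                      meta$record_id[miss], headers[miss]), collapse = ", "))
  meta$phylum[is.na(meta$phylum) | !nzchar(meta$phylum)] <- NA_character_
  if (imet_to_met) meta$amino_acid[meta$amino_acid == "iMet"] <- "Met"
  keep <- rep(TRUE, nrow(meta))
  if (drop_noncanonical) keep <- meta$amino_acid %in% AMINO_ACIDS
  trna_records(record_id = meta$record_id[keep],
               species_id = meta$species_id[keep],
               phylum = meta$phylum[keep],
               amino_acid = meta$amino_acid[keep],
               anticodon = meta$anticodon[keep],
               sequence = unname(seqs[keep]),
               anticodon_start = meta$anticodon_start[keep],
               intron_spans = spans[keep])
}

empty_records <- function() {
  df <- data.frame(record_id = character(), species_id = character(),
                   phylum = character(), amino_acid = character(),
                   anticodon = character(), sequence = character(),
                   anticodon_start = integer(), stringsAsFactors = FALSE)
  df$intron_spans <- list()
  class(df) <- c("trna_records", "data.frame")
  df
}

#' Write tRNA gene records to FASTA
#'
#' @param records a `trna_records` data frame.
#' @param path output file.
#' @param header_dialect `"pipe"` (5 pipe-separated fields) or `"keyvalue"`
#'   (also serializes `anticodon_start` and intron spans).
#' @return `path`, invisibly.
#' @export
write_trna_fasta <- function(records, path,
                             header_dialect = c("pipe", "keyvalue")) {
  header_dialect <- match.arg(header_dialect)
  if (header_dialect == "pipe") {
    hdr <- sprintf("%s|%s|%s|%s|%s", records$record_id, records$species_id,
                   ifelse(is.na(records$phylum), "", records$phylum),
                   records$amino_acid, records$anticodon)
  } else {
    hdr <- sprintf("id=%s species=%s aa=%s anticodon=%s",
                   records$record_id, records$species_id,
                   records$amino_acid, records$anticodon)
    hdr <- paste0(hdr, ifelse(is.na(records$phylum), "",
                              paste0(" phylum=", records$phylum)))
    hdr <- paste0(hdr, ifelse(is.na(records$anticodon_start), "",
                              paste0(" anticodon_start=",
                                     records$anticodon_start)))
    spans <- vapply(records$intron_spans, format_span_token, "")
    hdr <- paste0(hdr, ifelse(nzchar(spans), paste0(" introns=", spans), ""))
  }
  lines <- character(0)
  if (nrow(records) > 0)
    lines <- as.vector(rbind(paste0(">", hdr), records$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that enforce
#' unique leaf labels. Multifurcations are supported.
#'
#' @param path Newick file.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @param tree an [ape::phylo] tree or an [stats::hclust] dendrogram.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write delimited tables
#'
#' Tab-separated text with a header line; deterministic column order (the
#' data frame's own). Round-trips data frames of character/numeric columns.
#'
#' @param rows a data frame.
#' @param path file path.
#' @return `read_table_tsv`: a data frame.
#' @export
write_table_tsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run configuration
#'
#' Assembles and validates the knobs shared by the pipeline stages. The
#' candidate position set must exclude the anticodon (N34-N36).
#'
#' @param candidate_positions ordered character vector of position labels
#'   (default: the 43-position set from [default_candidate_positions()]).
#' @param conserved_exclusions labels excluded from the default candidate set.
#' @param morna_size number of informative positions retained (default 8).
#' @param cv_reps replicates for t-CV/s-CV (default 100).
#' @param cv_train_fraction training fraction for t-CV (default 2/3).
#' @param s_cv_train_species training species count for s-CV (default 57).
#' @param n_label_permutations label permutations for the null (default 50).
#' @param n_gamma_permutations leaf permutations for Baker's Gamma (default
#'   1000).
#' @param rng_seed master seed.
#' @param ensemble_pair_aggregation `"sum"`, `"mean"` or `"min_match"`.
#' @param missing_aa_policy `"skip"` or `"penalize"`.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(candidate_positions = NULL,
                       conserved_exclusions = DEFAULT_CONSERVED_EXCLUSIONS,
                       morna_size = 8L, cv_reps = 100L,
                       cv_train_fraction = 2 / 3,
                       s_cv_train_species = 57L,
                       n_label_permutations = 50L,
                       n_gamma_permutations = 1000L,
                       rng_seed = 1L,
                       ensemble_pair_aggregation = c("sum", "mean",
                                                     "min_match"),
                       missing_aa_policy = c("skip", "penalize")) {
  if (is.null(candidate_positions))
    candidate_positions <- default_candidate_positions(conserved_exclusions)
  cfg <- list(candidate_positions = candidate_positions,
              conserved_exclusions = conserved_exclusions,
              morna_size = as.integer(morna_size),
              cv_reps = as.integer(cv_reps),
              cv_train_fraction = cv_train_fraction,
              s_cv_train_species = as.integer(s_cv_train_species),
              n_label_permutations = as.integer(n_label_permutations),
              n_gamma_permutations = as.integer(n_gamma_permutations),
              rng_seed = as.integer(rng_seed),
              ensemble_pair_aggregation = match.arg(ensemble_pair_aggregation),
              missing_aa_policy = match.arg(missing_aa_policy))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (any(cfg$candidate_positions %in% ANTICODON_SLOTS))
    stop("candidate_positions must exclude the anticodon (N34-N36)")
  pos_num(cfg$candidate_positions)  # validates label syntax
  counts <- c(cfg$morna_size, cfg$cv_reps, cfg$s_cv_train_species,
              cfg$n_label_permutations, cfg$n_gamma_permutations)
  if (any(counts <= 0)) stop("all run_config counts must be positive")
  if (cfg$cv_train_fraction <= 0 || cfg$cv_train_fraction >= 1)
    stop("cv_train_fraction must lie in (0, 1)")
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg a `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
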