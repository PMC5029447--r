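# one canonical anticodon per amino acid (wobble realism is out of scope;
# the anticodon is excluded from all features anyway)
DEFAULT_ANTICODONS <- c(
  Ala = "AGC", Arg = "ACG", Asn = "GUU", Asp = "GUC", Cys = "GCA",
  Gln = "CUG", Glu = "CUC", Gly = "GCC", His = "GUG", Ile = "GAU",
  Leu = "CAG", Lys = "CUU", Met = "CAU", Phe = "GAA", Pro = "CGG",
  Ser = "CGA", Thr = "CGU", Trp = "CCA", Tyr = "GUA", Val = "GAC")

# classically invariant bases and their states, matching the default
# candidate-set exclusions
DEFAULT_CONSERVED_STATES <- c(
  N8 = "U", N14 = "A", N18 = "G", N19 = "G", N21 = "A",
  N54 = "U", N55 = "U", N56 = "C")

#' Specification of a synthetic tRNA-gene dataset
#'
#' Describes the generative model: two (or more) phylum-like clades of
#' species related by a random coalescent tree; per species and amino acid, a
#' small number of gene copies; a set of planted class-informative code
#' positions whose states are shared universally, per phylum, or drift along
#' the species tree; classically conserved positions with fixed states; all
#' other positions i.i.d. background over `{A,C,G,U}`.
#'
#' @param n_species number of species (default 30).
#' @param n_phyla number of phylum clades (default 2).
#' @param amino_acids class labels (default: the 20 canonical codes).
#' @param genes_per_aa integer range, gene copies per amino acid per species.
#' @param planted data frame with columns `position`, `scope`
#'   (`"universal"`, `"phylum"` or `"species_drift"`); default: eight
#'   universal positions `N1,N2,N3,N11,N22,N51,N70,N73`.
#' @param conserved named character vector of fixed states.
#' @param mu per-branch code mutation probability for `species_drift`
#'   positions.
#' @param epsilon per-site noise rate applied off the planted positions.
#' @param dloop_del_rate per-gene probability of deleting 1-2 D-loop bases.
#' @param intron_rate per-gene probability of carrying an intron (inserted
#'   after N37, the canonical location).
#' @param species_tree optional supplied tree (an [ape::phylo] whose first
#'   split separates the phyla) with a `phylum` attribute; by default a tree
#'   is simulated.
#' @param seed RNG seed.
#' @return a validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_species = 30L, n_phyla = 2L,
                       amino_acids = AMINO_ACIDS,
                       genes_per_aa = c(2L, 4L),
                       planted = data.frame(
                         position = c("N1", "N2", "N3", "N11", "N22", "N51",
                                      "N70", "N73"),
                         scope = "universal", stringsAsFactors = FALSE),
                       conserved = DEFAULT_CONSERVED_STATES,
                       mu = 0, epsilon = 0, dloop_del_rate = 0,
                       intron_rate = 0, species_tree = NULL, seed = 1L) {
  spec <- list(n_species = as.integer(n_species),
               n_phyla = as.integer(n_phyla),
               amino_acids = amino_acids,
               genes_per_aa = as.integer(genes_per_aa),
               planted = planted, conserved = conserved,
               mu = mu, epsilon = epsilon,
               dloop_del_rate = dloop_del_rate, intron_rate = intron_rate,
               species_tree = species_tree, seed = as.integer(seed))
  stopifnot(spec$n_species >= 2, spec$n_phyla >= 1,
            spec$n_phyla <= spec$n_species,
            all(c("position", "scope") %in% names(planted)),
            all(planted$scope %in% c("universal", "phylum", "species_drift")),
            all(spec$genes_per_aa >= 1))
  rates <- c(mu, epsilon, dloop_del_rate, intron_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  pn <- pos_num(planted$position)
  if (any(pn %in% 34:36)) stop("planted positions collide with the anticodon")
  if (any(planted$position %in% names(conserved)))
    stop("planted positions collide with conserved positions")
  if (any(pn < 1 | pn > 73)) stop("planted positions must lie in N1..N73")
  if (4^nrow(planted) < length(amino_acids))
    stop("too few planted positions to give ", length(amino_acids),
         " amino acids distinct codes (4^", nrow(planted), " combinations)")
  if (!all(amino_acids %in% names(DEFAULT_ANTICODONS)))
    stop("amino acids outside the canonical 20 are not supported")
  class(spec) <- "synth_spec"
  spec
}

#' Simulate a species tree with phylum clades
#'
#' A random rooted tree whose first split separates the phyla: each phylum is
#' an independent coalescent subtree (depth normalized to 1), and the phylum
#' subtrees hang off the root on positive branches.
#'
#' @param n_species total species.
#' @param n_phyla number of clades (species split as evenly as possible).
#' @param seed RNG seed (`NULL`: use the current RNG state).
#' @return list with `tree` (an [ape::phylo]) and `phylum` (named character
#'   vector, species -> phylum).
#' @export
simulate_species_tree <- function(n_species, n_phyla = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_phyla > n_species) stop("more phyla than species")
  sizes <- tabulate(rep_len(seq_len(n_phyla), n_species), n_phyla)
  sp_names <- sprintf("sp%02d", seq_len(n_species))
  phyla <- sprintf("Phy%d", seq_len(n_phyla))
  phylum <- rep(phyla, sizes)
  names(phylum) <- sp_names
  at <- 0L
  subs <- character(n_phyla)
  for (i in seq_len(n_phyla)) {
    tips <- sp_names[(at + 1):(at + sizes[i])]
    at <- at + sizes[i]
    if (sizes[i] == 1) {
      subs[i] <- paste0(tips, ":1")
    } else {
      tr <- ape::rcoal(sizes[i], tip.label = tips)
      tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
      subs[i] <- sub(";$", "", ape::write.tree(tr))
    }
  }
  nwk <- if (n_phyla == 1) paste0(subs, ";")
         else paste0("(", paste(paste0(subs, ":0.5"), collapse = ","), ");")
  list(tree = ape::read.tree(text = nwk), phylum = phylum)
}

# evolve one categorical state down the tree: each branch mutates the state
# with probability mu, to a uniformly chosen different state
evolve_state <- function(tree, root_state, mu, alphabet = c("A", "C", "G", "U")) {
  ntip <- ape::Ntip(tree)
  state <- character(ntip + tree$Nnode)
  state[ntip + 1L] <- root_state
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1]
    ch <- pre$edge[k, 2]
    s <- state[par]
    if (mu > 0 && stats::runif(1) < mu)
      s <- sample(setdiff(alphabet, s), 1)
    state[ch] <- s
  }
  stats::setNames(state[seq_len(ntip)], tree$tip.label)
}

# Draw one root code per amino acid over the planted positions, distinct
# across amino acids. Every planted position is made individually necessary:
# for position j, the amino-acid pair (2j-1, 2j) differs only at j, so no
# proper subset of the planted positions separates all classes. This mirrors
# the premise that different amino acids rely on different identity
# positions.
draw_root_codes <- function(aas, npos) {
  n <- length(aas)
  if (4^npos < n) stop("code space too small for ", n, " distinct classes")
  nt4 <- c("A", "C", "G", "U")
  repeat {
    m <- matrix(sample(nt4, n * npos, replace = TRUE),
                nrow = n, dimnames = list(aas, NULL))
    for (j in seq_len(min(npos, n %/% 2))) {
      m[2 * j, ] <- m[2 * j - 1, ]
      m[2 * j, j] <- sample(setdiff(nt4, m[2 * j - 1, j]), 1)
    }
    if (!anyDuplicated(apply(m, 1, paste, collapse = ""))) return(m)
  }
}

#' Generate a synthetic tRNA-gene dataset with ground truth
#'
#' Assembles, per species x amino acid x gene copy, a full 73-base gene
#' (canonical positions N1-N73, no gaps at generation) from the conserved
#' states, the amino acid's anticodon at N34-N36, the planted code states,
#' and i.i.d. background; then applies site noise off the planted positions,
#' optional D-loop deletions, appends the CCA tail and optionally inserts an
#' intron after N37. The truth bundle records every planted position, every
#' species' true codes, the species tree and the phylum map.
#'
#' @param spec a [synth_spec()].
#' @return list with `records` (a `trna_records` data frame) and `truth`
#'   (list: `planted`, `codes` data frame `species`, `amino_acid`, `code`,
#'   `tree`, `phylum`, `spec`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  if (is.null(spec$species_tree)) {
    st <- simulate_species_tree(spec$n_species, spec$n_phyla)
  } else {
    st <- list(tree = spec$species_tree,
               phylum = attr(spec$species_tree, "phylum"))
    if (is.null(st$phylum)) stop("supplied species_tree needs a phylum attribute")
  }
  tree <- st$tree
  phylum <- st$phylum
  species <- tree$tip.label
  aas <- spec$amino_acids
  planted <- spec$planted
  npos <- nrow(planted)
  nt4 <- c("A", "C", "G", "U")

  root <- draw_root_codes(aas, npos)
  # state[species, aa, pos]
  state <- array(NA_character_, dim = c(length(species), length(aas), npos),
                 dimnames = list(species, aas, planted$position))
  phyla <- unique(phylum)
  for (j in seq_len(npos)) {
    sc <- planted$scope[j]
    if (sc == "universal") {
      state[, , j] <- matrix(root[, j], nrow = length(species),
                             ncol = length(aas), byrow = TRUE)
    } else if (sc == "phylum") {
      for (pi in seq_along(phyla)) {
        sp_in <- species[phylum[species] == phyla[pi]]
        for (ai in seq_along(aas)) {
          s <- if (pi == 1) root[ai, j] else
            sample(setdiff(nt4, root[ai, j]), 1)
          state[sp_in, ai, j] <- s
        }
      }
    } else {  # species_drift
      for (ai in seq_along(aas)) {
        leaf <- evolve_state(tree, root[ai, j], spec$mu)
        state[names(leaf), ai, j] <- leaf
      }
    }
  }
  # keep per-phylum codes distinct across amino acids (resample drifted or
  # phylum states of colliding pairs at phylum-scope positions, if any)
  ph_cols <- which(planted$scope == "phylum")
  if (length(ph_cols)) {
    for (pi in seq_along(phyla)) {
      sp1 <- species[phylum[species] == phyla[pi]][1]
      for (it in 1:100) {
        codes <- apply(state[sp1, , , drop = FALSE], 2, paste, collapse = "")
        dup <- duplicated(codes) | duplicated(codes, fromLast = TRUE)
        if (!any(dup)) break
        for (ai in which(dup)) {
          j <- sample(ph_cols, 1)
          sp_in <- species[phylum[species] == phyla[pi]]
          state[sp_in, ai, j] <- sample(nt4, 1)
        }
      }
    }
  }

  dloop <- 14:21
  background <- setdiff(1:73, c(pos_num(planted$position), 34:36,
                                pos_num(names(spec$conserved))))
  n_copy_range <- spec$genes_per_aa
  rows <- list()
  truth_codes <- expand.grid(species = species, amino_acid = aas,
                             stringsAsFactors = FALSE)
  truth_codes$code <- vapply(seq_len(nrow(truth_codes)), function(i)
    paste(state[truth_codes$species[i], truth_codes$amino_acid[i], ],
          collapse = ""), "")

  for (sp in species) {
    for (ai in seq_along(aas)) {
      aa <- aas[ai]
      n_copy <- if (n_copy_range[1] == n_copy_range[2]) n_copy_range[1] else
        sample(n_copy_range[1]:n_copy_range[2], 1)
      for (cp in seq_len(n_copy)) {
        slots <- character(73)
        slots[background] <- sample(nt4, length(background), replace = TRUE)
        slots[pos_num(names(spec$conserved))] <- spec$conserved
        slots[34:36] <- strsplit(DEFAULT_ANTICODONS[[aa]], "")[[1]]
        slots[pos_num(planted$position)] <- state[sp, ai, ]
        if (spec$epsilon > 0) {
          noisy <- c(background, pos_num(names(spec$conserved)))
          flip <- noisy[stats::runif(length(noisy)) < spec$epsilon]
          for (f in flip) slots[f] <- sample(setdiff(nt4, slots[f]), 1)
        }
        ndel <- 0L
        if (spec$dloop_del_rate > 0 &&
            stats::runif(1) < spec$dloop_del_rate) {
          ndel <- sample(1:2, 1)
          slots <- slots[-sample(dloop, ndel)]
        }
        body <- paste(slots, collapse = "")
        ac_start <- 33L - ndel  # 0-based, on the intron-free gene body
        spans <- NULL
        if (spec$intron_rate > 0 && stats::runif(1) < spec$intron_rate) {
          ins <- 37L - ndel  # 0-based insertion point, after N37
          len <- sample(8:16, 1)
          intron <- paste(sample(nt4, len, replace = TRUE), collapse = "")
          body <- paste0(substr(body, 1, ins), intron,
                         substr(body, ins + 1, nchar(body)))
          spans <- matrix(c(ins, ins + len), 1, 2,
                          dimnames = list(NULL, c("start", "end")))
        }
        rows[[length(rows) + 1L]] <- list(
          record_id = sprintf("%s_%s_%d", sp, aa, cp),
          species_id = sp, phylum = unname(phylum[sp]), amino_acid = aa,
          anticodon = DEFAULT_ANTICODONS[[aa]],
          sequence = paste0(body, "CCA"),
          anticodon_start = ac_start, intron_spans = spans)
      }
    }
  }
  records <- trna_records(
    record_id = vapply(rows, `[[`, "", "record_id"),
    species_id = vapply(rows, `[[`, "", "species_id"),
    phylum = vapply(rows, `[[`, "", "phylum"),
    amino_acid = vapply(rows, `[[`, "", "amino_acid"),
    anticodon = vapply(rows, `[[`, "", "anticodon"),
    sequence = vapply(rows, `[[`, "", "sequence"),
    anticodon_start = vapply(rows, `[[`, 0L, "anticodon_start"),
    intron_spans = lapply(rows, `[[`, "intron_spans"))
  list(records = records,
       truth = list(planted = planted, codes = truth_codes, tree = tree,
                    phylum = phylum, spec = spec))
}

#' Precision and recall of selected positions against the planted truth
#'
#' @param truth a truth bundle from [generate_dataset()].
#' @param selected character vector of selected position labels, or a named
#'   list of such vectors (e.g. per amino acid).
#' @return data frame with `scope` (`"global"` or the list names),
#'   `n_selected`, `n_planted`, `precision`, `recall`.
#' @export
truth_recovery_report <- function(truth, selected) {
  planted <- truth$planted$position
  score_one <- function(sel) {
    hit <- length(intersect(sel, planted))
    c(n_selected = length(sel), n_planted = length(planted),
      precision = if (length(sel)) hit / length(sel) else NA_real_,
      recall = hit / length(planted))
  }
  if (!is.list(selected)) selected <- list(global = selected)
  out <- do.call(rbind, lapply(selected, score_one))
  data.frame(scope = names(selected), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
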