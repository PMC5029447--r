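PIPELINE_STAGES <- c("simulate", "prep", "select", "validate", "per_aa",
                     "ensemble_tree", "compare_trees")

#' Run the full identification pipeline
#'
#' Executes the stages in order — simulate (or read input), prep, select,
#' validate, per-amino-acid statistics, ensemble tree, tree comparison —
#' writing every intermediate artifact as a plain file (TSV / JSON / Newick /
#' FASTA) under `out_dir`, plus a JSON manifest with the configuration
#' snapshot, seed and MD5 checksums of all outputs. Reruns with the same seed
#' and configuration reproduce identical outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @param input_fasta optional input FASTA of tRNA gene records; when `NULL`
#'   the `simulate` stage generates a synthetic dataset.
#' @param synth a [synth_spec()] for the simulate stage (default:
#'   `synth_spec(seed = seed)`).
#' @param reference_newick optional reference phylogeny for the
#'   `compare_trees` stage; defaults to the synthetic truth tree when
#'   simulating, and is required otherwise.
#' @param stages subset of `simulate, prep, select, validate, per_aa,
#'   ensemble_tree, compare_trees` to run (in pipeline order; later stages
#'   require the earlier ones in the same call).
#' @param seed master seed (default: the config's).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(out_dir, config = run_config(), input_fasta = NULL,
                         synth = NULL, reference_newick = NULL,
                         stages = PIPELINE_STAGES, seed = config$rng_seed) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  state$reference <- NULL
  note <- function(stage, fmt, ...)
    message(sprintf("[%s] seed=%d %s", stage, seed, sprintf(fmt, ...)))
  out <- function(name) {
    path <- file.path(out_dir, name)
    outputs <<- c(outputs, path)
    path
  }
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible())
    tryCatch(fun(), error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  run_stage("simulate", function() {
    if (!is.null(input_fasta)) {
      state$records <- read_trna_fasta(input_fasta, "keyvalue")
      note("simulate", "read %d records from %s", nrow(state$records),
           input_fasta)
      return(invisible())
    }
    spec <- synth %||% synth_spec(seed = seed)
    gen <- generate_dataset(spec)
    state$records <- gen$records
    state$truth <- gen$truth
    state$reference <- gen$truth$tree
    write_trna_fasta(gen$records, out("genes.fasta"), "keyvalue")
    write_table_tsv(gen$truth$codes, out("truth_codes.tsv"))
    write_newick(gen$truth$tree, out("species_tree.nwk"))
    note("simulate", "generated %d records for %d species",
         nrow(gen$records), length(gen$truth$phylum))
  })

  run_stage("prep", function() {
    if (is.null(state$records)) stop("prep needs the simulate stage (or an input FASTA)")
    aligned <- prepare_records(state$records)
    state$tab <- extract_features(aligned, config$candidate_positions)
    write_table_tsv(cbind(record_id = rownames(aligned$slots),
                          as.data.frame(aligned$slots)),
                    out("aligned.tsv"))
    write_table_tsv(aligned$rejects, out("rejects.tsv"))
    write_table_tsv(cbind(aligned$meta, as.data.frame(state$tab$x)),
                    out("features.tsv"))
    note("prep", "read=%d retained=%d rejected=%d", nrow(state$records),
         nrow(state$tab$x), nrow(aligned$rejects))
  })

  run_stage("select", function() {
    if (is.null(state$tab)) stop("select needs the prep stage")
    trace <- forward_select(state$tab, config$morna_size)
    state$selected <- trace$selected
    write_table_tsv(trace$steps, out("selection_trace.tsv"))
    yaml::write_yaml(list(morna_positions = trace$selected),
                     out("selected_positions.yaml"))
    note("select", "selected %s (accuracy %.4f)",
         paste(trace$selected, collapse = ","),
         tail(trace$steps$accuracy, 1))
  })

  run_stage("validate", function() {
    if (is.null(state$tab)) stop("validate needs the prep stage")
    tab <- state$tab
    k <- config$morna_size
    tcv <- t_cv(tab, frac = config$cv_train_fraction, reps = config$cv_reps,
                k = k, seed = seed)
    n_sp <- length(unique(tab$species))
    scv <- s_cv(tab, n_train_species = min(config$s_cv_train_species,
                                           n_sp - 1L),
                reps = config$cv_reps, k = k, seed = seed)
    res <- list(t_cv = tcv$mean_accuracy, s_cv = scv$mean_accuracy)
    reps <- data.frame(scheme = rep(c("t_cv", "s_cv"),
                                    c(length(tcv$accuracies),
                                      length(scv$accuracies))),
                       accuracy = c(tcv$accuracies, scv$accuracies))
    if (length(unique(tab$phylum[!is.na(tab$phylum)])) >= 2) {
      fcv <- f_cv(tab, k = k)
      res$f_cv <- as.list(fcv$accuracies)
      reps <- rbind(reps, data.frame(scheme = "f_cv",
                                     accuracy = fcv$accuracies))
    }
    pn <- permutation_null(tab, n_perm = config$n_label_permutations, k = k,
                           seed = seed)
    res$null_resub <- pn$mean_resub
    res$null_cv <- pn$mean_cv
    write_table_tsv(reps, out("cv_replicates.tsv"))
    jsonlite::write_json(res, out("validation.json"), auto_unbox = TRUE,
                         digits = NA)
    note("validate", "t_cv=%.4f s_cv=%.4f null_cv=%.4f", res$t_cv, res$s_cv,
         res$null_cv)
  })

  run_stage("per_aa", function() {
    if (is.null(state$tab)) stop("per_aa needs the prep stage")
    tab <- state$tab
    grid <- screen_positions(tab)
    write_table_tsv(cbind(amino_acid = rownames(grid), as.data.frame(grid)),
                    out("cramers_v_grid.tsv"))
    summ <- lapply(rownames(grid), function(aa) {
      j <- which.max(grid[aa, ])
      st <- single_rule_stats(tab, aa, colnames(grid)[j])
      data.frame(amino_acid = aa, position = st$position,
                 nucleotide = st$nucleotide, cramers_v = st$cramers_v,
                 sensitivity = st$sensitivity, ppv = st$ppv,
                 stringsAsFactors = FALSE)
    })
    write_table_tsv(do.call(rbind, summ), out("single_position_stats.tsv"))
    mm <- lapply(rownames(grid), function(aa) {
      m <- per_aa_minimal_model(tab, aa)
      data.frame(amino_acid = aa, k = m$k, x0 = m$x0, met = m$met,
                 positions = paste(m$positions, collapse = ","),
                 accuracy = if (m$k > 0) m$curve$accuracy[m$k] else m$x0,
                 stringsAsFactors = FALSE)
    })
    write_table_tsv(do.call(rbind, mm), out("minimal_models.tsv"))
    note("per_aa", "screened %d classes x %d positions", nrow(grid),
         ncol(grid))
  })

  run_stage("ensemble_tree", function() {
    if (is.null(state$selected)) stop("ensemble_tree needs the select stage")
    ens <- build_ensembles(state$tab, state$selected)
    d <- distance_matrix(ens, config$ensemble_pair_aggregation,
                         config$missing_aa_policy)
    state$morna_tree <- complete_linkage(d)
    long <- do.call(rbind, lapply(names(ens$ensembles), function(sp)
      do.call(rbind, lapply(names(ens$ensembles[[sp]]), function(aa)
        data.frame(species = sp, amino_acid = aa,
                   code = ens$ensembles[[sp]][[aa]],
                   stringsAsFactors = FALSE)))))
    write_table_tsv(long, out("ensembles.tsv"))
    write_table_tsv(cbind(species = rownames(d), as.data.frame(d)),
                    out("distance_matrix.tsv"))
    write_newick(state$morna_tree, out("morna_tree.nwk"))
    note("ensemble_tree", "%d species, %d unique codes",
         length(ens$ensembles), ens$census$n_unique_codes)
  })

  run_stage("compare_trees", function() {
    if (is.null(state$morna_tree)) stop("compare_trees needs the ensemble_tree stage")
    ref <- if (!is.null(reference_newick)) read_newick(reference_newick)
           else state$reference
    if (is.null(ref))
      stop("no reference phylogeny: supply reference_newick")
    gt <- gamma_permutation_test(state$morna_tree, ref,
                                 n_perm = config$n_gamma_permutations,
                                 seed = seed)
    jsonlite::write_json(list(gamma = gt$gamma, p_value = gt$p_value,
                              null_quantiles = as.list(gt$null_quantiles)),
                         out("gamma.json"), auto_unbox = TRUE, digits = NA)
    write_table_tsv(tanglegram_pairing(state$morna_tree, ref),
                    out("tanglegram_pairing.tsv"))
    note("compare_trees", "gamma=%.4f p=%.4g", gt$gamma, gt$p_value)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("trnacipher")),
    seed = seed,
    config = unclass(config),
    stages = stages,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
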