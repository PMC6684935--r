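PIPELINE_STAGES <- c("simulate", "select", "treeclean", "concat", "recode",
                     "saturation")

#' Pipeline configuration
#'
#' Bundles per-stage settings for [run_pipeline()]. Serialises losslessly to
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param stages subset of `r paste(PIPELINE_STAGES, collapse = ", ")`, run
#'   in that order.
#' @param sim list of [sim_config()] arguments.
#' @param selection list of [selection_config()] arguments.
#' @param long_branch list of [long_branch_policy()] arguments.
#' @param occupancy minimum taxon fraction for the gene filter.
#' @param recode_scheme recoding scheme name (`"dayhoff6"`) or a scheme
#'   config list for [read_recoding_scheme()].
#' @param max_gap_fraction optional column-gappiness threshold for
#'   [simple_column_filter()]; NULL skips column trimming.
#' @param seed integer seed; identical config + seed gives identical output
#'   hashes.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = PIPELINE_STAGES,
                            sim = list(), selection = list(),
                            long_branch = list(), occupancy = 0.5,
                            recode_scheme = "dayhoff6",
                            max_gap_fraction = NULL, seed = 1L) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stopifnot(occupancy >= 0, occupancy <= 1)
  structure(list(stages = stages, sim = sim, selection = selection,
                 long_branch = long_branch, occupancy = occupancy,
                 recode_scheme = recode_scheme,
                 max_gap_fraction = max_gap_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a written synthetic dataset back from disk
#'
#' Counterpart of [write_dataset()]: reloads gene families, hit tables,
#' gene trees, species tree and truth tables, so later stages can run
#' standalone on a previous run's files.
#'
#' @param directory dataset directory containing `manifest.tsv`.
#' @return a `synthetic_dataset`-shaped list (without `config`).
#' @export
read_dataset <- function(directory) {
  man <- file.path(directory, "manifest.tsv")
  if (!file.exists(man)) abort(paste0("no manifest at: ", man))
  genes <- sub("\\.fasta$", "",
               list.files(file.path(directory, "genes"), pattern = "\\.fasta$"))
  families <- map(genes, function(g) {
    seqs <- read_fasta(file.path(directory, "genes", paste0(g, ".fasta")))
    gene_family(g, tibble(taxon_id = taxon_from_seq_id(names(seqs)),
                          seq_id = names(seqs), sequence = unname(seqs)))
  })
  hits <- map(genes, function(g) {
    read_hit_table(file.path(directory, "hits", paste0(g, ".tsv")),
                   gene_id = g)
  })
  gtrees <- map(genes, function(g) {
    ape::read.tree(file.path(directory, "gene_trees", paste0(g, ".nwk")))
  })
  truth_path <- file.path(directory, "truth.tsv")
  structure(list(
    species_tree = ape::read.tree(file.path(directory, "species_tree.nwk")),
    gene_families = setNames(families, genes),
    gene_trees = setNames(gtrees, genes),
    hit_tables = setNames(hits, genes),
    truth = if (file.exists(truth_path))
      as_tibble(utils::read.table(truth_path, header = TRUE, sep = "\t"))
  ), class = "synthetic_dataset")
}

# subset simulated families to the resolved one-per-taxon members
resolved_families <- function(dataset, resolved) {
  keep_genes <- unique(resolved$gene_id)
  out <- map(keep_genes, function(g) {
    gf <- dataset$gene_families[[g]]
    sel <- resolved$seq_id[resolved$gene_id == g]
    gene_family(g, gf$members[gf$members$seq_id %in% sel, , drop = FALSE],
                aligned = gf$aligned)
  })
  setNames(out, keep_genes)
}

#' Run the assembly-and-diagnostics pipeline
#'
#' Executes the enabled stages in order — simulate, select (candidate
#' selection from hit tables), treeclean (long-branch screening during
#' ortholog resolution), concat (occupancy filter + concatenation), recode
#' (Dayhoff-6), saturation (p-distance vs patristic regression against the
#' species tree) — writing every intermediate under `out_dir` and a
#' `manifest.tsv` of file MD5 hashes. Identical config + seed reproduces
#' identical hashes.
#'
#' @param config a [pipeline_config()] or YAML path.
#' @param out_dir output directory (created if absent).
#' @param dataset optional pre-built `synthetic_dataset`; when NULL and the
#'   simulate stage is off, a dataset is read from `file.path(out_dir,
#'   "data")`.
#' @param quiet suppress progress messages.
#' @return tibble manifest (file, md5), invisibly; also written to
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         dataset = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) abort(paste0("cannot create directory: ", out_dir))
  say <- function(...) if (!quiet) message("[supersat] ", ...)
  files <- character(0)
  emit <- function(rel) files <<- c(files, rel)
  stage <- function(name) name %in% config$stages
  fail <- function(name, e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  }

  set.seed(config$seed)
  if (stage("simulate")) {
    say("simulate: generating synthetic dataset (seed ", config$seed, ")")
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    dataset <- tryCatch(simulate_dataset(scfg),
                        error = function(e) fail("simulate", e))
    write_dataset(dataset, file.path(out_dir, "data"))
    emit(file.path("data", readLines(file.path(out_dir, "data", "manifest.tsv"))[-1L]))
  } else if (is.null(dataset)) {
    dataset <- read_dataset(file.path(out_dir, "data"))
  }

  resolved <- NULL
  if (stage("select")) {
    say("select: e-value ceiling + window candidate selection")
    sel_cfg <- do.call(selection_config, config$selection)
    lb_pol <- do.call(long_branch_policy, config$long_branch)
    hits <- bind_rows(imap(dataset$hit_tables, function(h, g) {
      as_hit_table(h, gene_id = g)
    }))
    trees <- if (stage("treeclean")) dataset$gene_trees
    res <- tryCatch({
      cand <- select_candidates(hits, sel_cfg)
      resolved <- suppressWarnings(resolve_orthologs(cand, trees, lb_pol))
      list(cand = cand, resolved = resolved)
    }, error = function(e) fail("select", e))
    resolved <- res$resolved
    report <- selection_report(res$cand, resolved, trees, lb_pol)
    write_tsv_plain(report, file.path(out_dir, "selection_report.tsv"))
    emit("selection_report.tsv")
    if (!is.null(trees)) {
      lb <- bind_rows(imap(trees, function(tr, g) {
        suppressWarnings(long_branch_report(tr, lb_pol, gene_id = g))
      }))
      write_tsv_plain(lb, file.path(out_dir, "long_branch_report.tsv"))
      emit("long_branch_report.tsv")
    }
  }

  sm <- NULL
  if (stage("concat")) {
    say("concat: occupancy filter + concatenation")
    fams <- if (!is.null(resolved)) resolved_families(dataset, resolved) else
      dataset$gene_families
    universe <- sort(dataset$species_tree$tip.label)
    sm <- tryCatch({
      kept <- occupancy_filter(fams, config$occupancy, universe)
      if (!length(kept)) abort("no genes survive the occupancy filter")
      concatenate(kept)
    }, error = function(e) fail("concat", e))
    if (!is.null(config$max_gap_fraction)) {
      sm <- simple_column_filter(sm, config$max_gap_fraction)
    }
    write_supermatrix(sm, file.path(out_dir, "supermatrix.fasta"))
    occ <- occupancy_report(sm)
    write_tsv_plain(occ$per_gene, file.path(out_dir, "occupancy_genes.tsv"))
    write_tsv_plain(occ$per_taxon, file.path(out_dir, "occupancy_taxa.tsv"))
    emit(c("supermatrix.fasta", "supermatrix.fasta.partitions",
           "occupancy_genes.tsv", "occupancy_taxa.tsv"))
    say(sprintf("concat: %d taxa x %d columns, %.1f%% complete",
                nrow(sm$matrix), ncol(sm$matrix), occ$completeness))
  }

  if (stage("recode")) {
    if (is.null(sm)) abort("stage 'recode' failed: no supermatrix available")
    say("recode: applying 6-state recoding")
    scheme <- if (is.character(config$recode_scheme) &&
                    config$recode_scheme == "dayhoff6") dayhoff6() else
      read_recoding_scheme(config$recode_scheme)
    rc <- tryCatch(recode(sm, scheme), error = function(e) fail("recode", e))
    write_supermatrix(rc, file.path(out_dir, "supermatrix_recoded.phy"),
                      format = "phylip")
    emit(c("supermatrix_recoded.phy", "supermatrix_recoded.phy.partitions"))
  }

  if (stage("saturation")) {
    if (is.null(sm)) abort("stage 'saturation' failed: no supermatrix available")
    say("saturation: p-distance vs patristic regression")
    fit <- tryCatch(
      saturation_fit(p_distance_matrix(sm),
                     patristic_matrix(dataset$species_tree)),
      error = function(e) fail("saturation", e))
    write_tsv_plain(fit$pairs, file.path(out_dir, "saturation_pairs.tsv"))
    write_tsv_plain(glance(fit), file.path(out_dir, "saturation_fit.tsv"))
    emit(c("saturation_pairs.tsv", "saturation_fit.tsv"))
    say(sprintf("saturation: R^2 = %.3f over %d pairs", fit$r_squared,
                fit$pairs_used))
  }

  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))
  say("done: ", length(files), " files in ", out_dir)
  invisible(manifest)
}
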