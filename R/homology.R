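BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")

#' Read and write BLAST-tabular hit files
#'
#' The 12-column tab-separated dialect (`-outfmt 6`): qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore, no
#' header. `read_hit_table()` additionally derives `gene_id`, `taxon_id`,
#' `seq_id`, `query_length` and `subject_length` columns, which the selection
#' functions require; by default the subject id is parsed as
#' `<taxon>_<gene>_<copy>` (the synthetic dataset's convention) but both
#' fields can be supplied via labelling functions for other naming schemes.
#'
#' @param path file path.
#' @param gene_id gene identifier for all rows of the file; defaults to the
#'   file name without extension.
#' @param taxon_fun function mapping subject ids to taxon ids.
#' @param hits a hit tibble whose first 12 columns are the BLAST fields.
#' @return `read_hit_table()` a tibble; `write_hit_table()` the path,
#'   invisibly.
#' @export
read_hit_table <- function(path, gene_id = NULL,
                           taxon_fun = taxon_from_seq_id) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = BLAST_COLS,
                          colClasses = c("character", "character",
                                         rep("numeric", 10)))
  gene_id <- gene_id %||% sub("\\.[^.]*$", "", basename(path))
  as_hit_table(as_tibble(df), gene_id = gene_id, taxon_fun = taxon_fun)
}

#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, BLAST_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coerce BLAST columns to the internal hit-table layout
#'
#' Validates e-values and lengths and adds the bookkeeping columns used by
#' [apply_evalue_ceiling()] and [select_candidates()]: `gene_id`, `seq_id`,
#' `taxon_id`, `query_length` and `subject_length`. With ungapped full-length
#' hits both lengths equal the alignment `length` column, which is used for
#' either when no explicit length is available.
#'
#' @param hits tibble with at least `sseqid` and `evalue` columns.
#' @param gene_id gene id recycled over rows (ignored when a `gene_id`
#'   column is present).
#' @param taxon_fun function mapping subject ids to taxon ids (ignored when
#'   a `taxon_id` column is present).
#' @return a hit tibble.
#' @export
as_hit_table <- function(hits, gene_id = NULL,
                         taxon_fun = taxon_from_seq_id) {
  hits <- as_tibble(hits)
  if (!"gene_id" %in% names(hits)) {
    if (is.null(gene_id)) abort("hit table needs a gene_id")
    hits$gene_id <- gene_id
  }
  if (!"seq_id" %in% names(hits)) hits$seq_id <- hits$sseqid
  if (!"taxon_id" %in% names(hits)) hits$taxon_id <- taxon_fun(hits$seq_id)
  if (!"query_length" %in% names(hits)) hits$query_length <- hits$length
  if (!"subject_length" %in% names(hits)) hits$subject_length <- hits$length
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    abort("data error: negative e-value in hit table")
  }
  lens <- c(hits$query_length, hits$subject_length)
  if (any(lens <= 0, na.rm = TRUE)) {
    abort("data error: non-positive sequence length in hit table")
  }
  dup <- duplicated(hits[, c("gene_id", "seq_id")])
  if (any(dup)) {
    abort(paste0("data error: duplicated (gene_id, seq_id): ",
                 paste(head(hits$seq_id[dup], 3L), collapse = ", ")))
  }
  invisible(hits)
}

#' Ortholog-selection configuration
#'
#' Rules for picking candidate orthologs from homology hits: a hard
#' length-dependent e-value ceiling, then per taxon the best hit plus all
#' hits within `window_orders` orders of magnitude of it. The defaults are
#' the conventional thresholds for expanding a curated phylogenomic gene set:
#' hits for proteins shorter than 150 residues must reach 1e-20, longer
#' proteins the stricter 1e-80, and near-ties within three orders of
#' magnitude are retained as alternative orthologs.
#'
#' @param window_orders orders of magnitude around the best e-value within
#'   which alternatives are kept (>= 0).
#' @param short_len_cutoff length (residues) below which the lenient ceiling
#'   applies; proteins of exactly this length use the strict ceiling.
#' @param evalue_max_short ceiling for short proteins.
#' @param evalue_max_long ceiling for long proteins (must be <= the short
#'   ceiling).
#' @param length_field which length the ceiling tests: the `"subject"`
#'   (candidate) or `"query"` protein.
#' @param scope apply the window per `"taxon"` (default) or per `"gene"`
#'   across all taxa.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(window_orders = 3,
                             short_len_cutoff = 150L,
                             evalue_max_short = 1e-20,
                             evalue_max_long = 1e-80,
                             length_field = c("subject", "query"),
                             scope = c("taxon", "gene")) {
  if (window_orders < 0) abort("window_orders must be >= 0")
  if (!(evalue_max_long > 0 && evalue_max_long <= evalue_max_short &&
          evalue_max_short <= 1)) {
    abort("need 0 < evalue_max_long <= evalue_max_short <= 1")
  }
  structure(list(window_orders = window_orders,
                 short_len_cutoff = as.integer(short_len_cutoff),
                 evalue_max_short = evalue_max_short,
                 evalue_max_long = evalue_max_long,
                 length_field = match.arg(length_field),
                 scope = match.arg(scope)),
            class = "selection_config")
}

#' Filter hits by the length-dependent e-value ceiling
#'
#' Retains a hit iff its e-value is at or below the ceiling for its protein
#' length: `evalue_max_short` when the reference length is strictly below
#' `short_len_cutoff`, `evalue_max_long` otherwise. Idempotent.
#'
#' @param hits a hit tibble (see [as_hit_table()]).
#' @param config a [selection_config()].
#' @return the filtered hit tibble.
#' @export
apply_evalue_ceiling <- function(hits, config = selection_config()) {
  hits <- as_hit_table(hits)
  ref_len <- if (config$length_field == "subject") hits$subject_length else
    hits$query_length
  ceiling_ <- ifelse(ref_len < config$short_len_cutoff,
                     config$evalue_max_short, config$evalue_max_long)
  hits[hits$evalue <= ceiling_, , drop = FALSE]
}

#' Select candidate orthologs per taxon
#'
#' Within each (gene, taxon) group — or per gene when `config$scope` is
#' `"gene"` — keeps the minimum-e-value hit together with every hit whose
#' e-value is within `window_orders` orders of magnitude of it
#' (`evalue <= best * 10^window_orders`, inclusive). An exact e-value of 0 is
#' treated as below every positive value, and a window anchored at 0 retains
#' only other zero hits. Results are ranked best-first with deterministic
#' (evalue, seq_id) tie-breaking, so the output is invariant to input row
#' order.
#'
#' @param hits a hit tibble.
#' @param config a [selection_config()].
#' @param apply_ceiling apply [apply_evalue_ceiling()] first (default TRUE).
#' @return tibble with columns gene_id, taxon_id, seq_id, evalue, rank.
#' @export
select_candidates <- function(hits, config = selection_config(),
                              apply_ceiling = TRUE) {
  hits <- as_hit_table(hits)
  if (apply_ceiling) hits <- apply_evalue_ceiling(hits, config)
  grp <- if (config$scope == "taxon") c("gene_id", "taxon_id") else "gene_id"
  out <- hits %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    filter(if (min(.data$evalue) == 0) .data$evalue == 0 else
      .data$evalue <= min(.data$evalue) * 10^config$window_orders) %>%
    arrange(.data$evalue, .data$seq_id, .by_group = TRUE) %>%
    mutate(rank = row_number()) %>%
    ungroup()
  out %>% select("gene_id", "taxon_id", "seq_id", "evalue", "rank")
}

#' Resolve one ortholog per taxon per gene
#'
#' From ranked candidates, selects for every (gene, taxon) the best-ranked
#' candidate that is not flagged as a long branch in the corresponding gene
#' tree (see [flag_long_branches()]); taxa whose candidates are all flagged
#' are dropped from the gene. When no tree is available for a gene, its best
#' candidates are taken as-is.
#'
#' @param candidates output of [select_candidates()].
#' @param gene_trees named list of `phylo` objects (tips labelled by
#'   candidate sequence id), or NULL to skip tree-based screening.
#' @param policy a [long_branch_policy()].
#' @return tibble gene_id, taxon_id, seq_id, evalue with one row per
#'   retained (gene, taxon) slot.
#' @export
resolve_orthologs <- function(candidates, gene_trees = NULL,
                              policy = long_branch_policy()) {
  stopifnot(all(c("gene_id", "taxon_id", "seq_id", "rank") %in%
                  names(candidates)))
  flagged <- character(0)
  if (!is.null(gene_trees)) {
    for (g in intersect(unique(candidates$gene_id), names(gene_trees))) {
      tree <- gene_trees[[g]]
      cand_g <- candidates$seq_id[candidates$gene_id == g]
      missing <- setdiff(cand_g, tree$tip.label)
      if (length(missing)) {
        abort(paste0("labeling error: candidates of gene '", g,
                     "' absent from its tree: ",
                     paste(head(missing, 5L), collapse = ", ")))
      }
      flagged <- c(flagged, paste0(g, "\r", flag_long_branches(tree, policy)))
    }
  }
  candidates %>%
    filter(!paste0(.data$gene_id, "\r", .data$seq_id) %in% flagged) %>%
    group_by(.data$gene_id, .data$taxon_id) %>%
    slice(which.min(.data$rank)) %>%
    ungroup() %>%
    select("gene_id", "taxon_id", "seq_id", "evalue")
}

#' Tabulate a selection run for reporting
#'
#' Joins candidates with the resolved choice into a per-candidate report:
#' kept (selected), flagged (long branch), or outranked.
#'
#' @param candidates output of [select_candidates()].
#' @param resolved output of [resolve_orthologs()].
#' @param gene_trees,policy as in [resolve_orthologs()] (used to recompute
#'   flags for the report); NULL omits flag status.
#' @return tibble gene_id, taxon_id, seq_id, evalue, rank, status.
#' @export
selection_report <- function(candidates, resolved, gene_trees = NULL,
                             policy = long_branch_policy()) {
  flagged <- character(0)
  if (!is.null(gene_trees)) {
    for (g in intersect(unique(candidates$gene_id), names(gene_trees))) {
      flagged <- c(flagged,
                   paste0(g, "\r",
                          flag_long_branches(gene_trees[[g]], policy)))
    }
  }
  candidates %>%
    mutate(status = dplyr::case_when(
      paste0(.data$gene_id, "\r", .data$seq_id) %in%
        paste0(resolved$gene_id, "\r", resolved$seq_id) ~ "kept",
      paste0(.data$gene_id, "\r", .data$seq_id) %in% flagged ~ "flagged",
      TRUE ~ "outranked"))
}
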