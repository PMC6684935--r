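MISSING_CHARS <- c("?", "-", "X")

#' Concatenate aligned gene families into a supermatrix
#'
#' Builds the classic partitioned supermatrix: taxa are the union over genes
#' (sorted lexicographically for byte-stable output), each gene occupies a
#' contiguous 1-based inclusive column span recorded in the partition table,
#' and taxa absent from a gene are padded with `'?'`.
#'
#' @param genes list of aligned [gene_family()] objects, each with one
#'   sequence per taxon.
#' @return an object of class `supermatrix`: list with `matrix` (character
#'   matrix, rows = taxa) and `partitions` (tibble gene_id, start, end).
#' @export
concatenate <- function(genes) {
  if (inherits(genes, "gene_family")) genes <- list(genes)
  stopifnot(length(genes) >= 1L)
  for (gf in genes) {
    if (!inherits(gf, "gene_family")) abort("concatenate() needs gene_family objects")
    if (!gf$aligned) {
      abort(paste0("alignment error: gene '", gf$gene_id, "' is not aligned"))
    }
    if (anyDuplicated(gf$members$taxon_id)) {
      abort(paste0("alignment error: gene '", gf$gene_id,
                   "' has multiple sequences for a taxon; resolve first"))
    }
  }
  ids <- unname(map_chr(genes, "gene_id"))
  if (anyDuplicated(ids)) abort("duplicated gene_id among gene families")
  taxa <- sort(unique(unlist(map(genes, function(g) g$members$taxon_id))))
  widths <- map_int(genes, function(g) {
    if (is.na(g$alignment_length)) 0L else g$alignment_length
  })
  total <- sum(widths)
  m <- matrix("?", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  ends <- unname(cumsum(widths))
  starts <- ends - unname(widths) + 1L
  for (i in seq_along(genes)) {
    if (widths[i] == 0L) next
    blk <- as_alignment_matrix(genes[[i]])
    m[rownames(blk), starts[i]:ends[i]] <- blk
  }
  new_supermatrix(m, tibble(gene_id = ids, start = starts, end = ends))
}

new_supermatrix <- function(m, partitions) {
  structure(list(matrix = m, partitions = partitions), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", nrow(x$matrix), " taxa x ", ncol(x$matrix),
      " columns, ", nrow(x$partitions), " partitions, ",
      sprintf("%.1f%%", completeness(x)), " complete\n", sep = "")
  invisible(x)
}

#' Matrix completeness
#'
#' Percentage of cells that carry data, i.e. are not one of the missing-data
#' symbols. The default set `{'?', '-', 'X'}` treats unknown residues as
#' missing; pass `missing_chars = c("?", "-")` to count `'X'` as data.
#'
#' @param x a `supermatrix`, character matrix, or aligned [gene_family()].
#' @param missing_chars symbols counted as missing.
#' @return completeness percentage in \[0, 100\].
#' @export
completeness <- function(x, missing_chars = MISSING_CHARS) {
  m <- as_alignment_matrix(x)
  if (length(m) == 0L) return(100)
  100 * sum(!(m %in% missing_chars)) / length(m)
}

#' Occupancy filter on gene families
#'
#' Keeps genes whose taxa cover at least `min_taxon_fraction` of the taxon
#' universe (inclusive at the boundary), the usual ">= 50% of taxa" gene
#' filter applied to de novo orthogroups before concatenation.
#'
#' @param genes list of [gene_family()] objects.
#' @param min_taxon_fraction minimum fraction of the universe, in \[0, 1\].
#' @param taxon_universe taxa against which occupancy is measured; defaults
#'   to the union of taxa over `genes`.
#' @return the retained sublist of `genes`.
#' @export
occupancy_filter <- function(genes, min_taxon_fraction = 0.5,
                             taxon_universe = NULL) {
  taxon_universe <- taxon_universe %||%
    sort(unique(unlist(map(genes, function(g) g$members$taxon_id))))
  if (!length(taxon_universe)) abort("taxon universe is empty")
  frac <- map_dbl(genes, function(g) {
    length(intersect(unique(g$members$taxon_id), taxon_universe)) /
      length(taxon_universe)
  })
  genes[frac >= min_taxon_fraction]
}

#' Per-gene and per-taxon occupancy report
#'
#' @param sm a `supermatrix`.
#' @param missing_chars symbols counted as missing.
#' @return list of tibbles: `per_gene` (gene_id, n_taxa_present,
#'   taxon_fraction), `per_taxon` (taxon_id, n_genes_present,
#'   gene_fraction), and `completeness` (percent scalar).
#' @export
occupancy_report <- function(sm, missing_chars = MISSING_CHARS) {
  stopifnot(inherits(sm, "supermatrix"))
  m <- sm$matrix
  part <- sm$partitions
  present <- matrix(FALSE, nrow(m), nrow(part),
                    dimnames = list(rownames(m), part$gene_id))
  for (i in seq_len(nrow(part))) {
    blk <- m[, part$start[i]:part$end[i], drop = FALSE]
    present[, i] <- rowSums(matrix(!(blk %in% missing_chars), nrow(m))) > 0
  }
  list(
    per_gene = tibble(gene_id = part$gene_id,
                      n_taxa_present = colSums(present),
                      taxon_fraction = colSums(present) / nrow(m)),
    per_taxon = tibble(taxon_id = rownames(m),
                       n_genes_present = rowSums(present),
                       gene_fraction = rowSums(present) / nrow(part)),
    completeness = completeness(sm, missing_chars)
  )
}

#' Drop gappy columns from a supermatrix
#'
#' Removes columns whose fraction of missing cells exceeds
#' `max_gap_fraction` and re-spans the partition table. A light stand-in for
#' external alignment trimmers; it makes no attempt to reproduce their
#' block-based heuristics. Genes losing every column are dropped from the
#' partition table.
#'
#' @param sm a `supermatrix`.
#' @param max_gap_fraction maximum tolerated missing fraction per column, in
#'   \[0, 1\].
#' @param missing_chars symbols counted as missing.
#' @return the filtered `supermatrix`.
#' @export
simple_column_filter <- function(sm, max_gap_fraction,
                                 missing_chars = MISSING_CHARS) {
  stopifnot(inherits(sm, "supermatrix"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- sm$matrix
  gap_frac <- colMeans(matrix(m %in% missing_chars, nrow(m)))
  keep <- gap_frac <= max_gap_fraction
  part <- sm$partitions
  kept_per_gene <- map_int(seq_len(nrow(part)), function(i) {
    sum(keep[part$start[i]:part$end[i]])
  })
  new_ends <- cumsum(kept_per_gene)
  new_starts <- new_ends - kept_per_gene + 1L
  surv <- kept_per_gene > 0L
  new_supermatrix(
    m[, keep, drop = FALSE],
    tibble(gene_id = part$gene_id[surv],
           start = new_starts[surv], end = new_ends[surv])
  )
}

#' Write and read a supermatrix
#'
#' The alignment is written as FASTA or relaxed PHYLIP together with a
#' RAxML-style partition file (`GENE1 = 1-100`), or as a NEXUS file with a
#' `sets` block of charsets. `read_supermatrix()` reassembles the object
#' from an alignment plus partition file and round-trips cells, taxon order
#' and partitions.
#'
#' @param sm a `supermatrix`.
#' @param path alignment file path (partition file defaults to
#'   `<path>.partitions` for fasta/phylip).
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param partitions_path partition file path.
#' @return written paths (invisibly) / the reassembled `supermatrix`.
#' @export
write_supermatrix <- function(sm, path,
                              format = c("fasta", "phylip", "nexus"),
                              partitions_path = paste0(path, ".partitions")) {
  stopifnot(inherits(sm, "supermatrix"))
  format <- match.arg(format)
  seqs <- alignment_strings(sm$matrix)
  if (format == "nexus") {
    write_nexus_supermatrix(sm, path)
    return(invisible(path))
  }
  if (format == "fasta") write_fasta(seqs, path) else write_phylip(seqs, path)
  write_partitions(sm$partitions, partitions_path)
  invisible(c(path, partitions_path))
}

#' @rdname write_supermatrix
#' @export
read_supermatrix <- function(path, partitions_path = paste0(path, ".partitions"),
                             format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- if (format == "fasta") read_fasta(path) else read_phylip(path)
  part <- read_partitions(partitions_path)
  new_supermatrix(as_alignment_matrix(seqs), part)
}

#' RAxML-style partition files
#'
#' One line per gene, `GENE = start-end`, 1-based inclusive.
#'
#' @param partitions tibble gene_id, start, end.
#' @param path file path.
#' @return path / partitions tibble.
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("%s = %d-%d", partitions$gene_id,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$", lines))
  bad <- map_lgl(m, function(x) length(x) != 4L)
  if (any(bad)) abort(paste0("cannot parse partition line: ", lines[bad][1L]))
  tibble(gene_id = map_chr(m, 2L),
         start = as.integer(map_chr(m, 3L)),
         end = as.integer(map_chr(m, 4L)))
}

write_nexus_supermatrix <- function(sm, path) {
  seqs <- alignment_strings(sm$matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(sm$matrix), ncol(sm$matrix)),
    "  FORMAT DATATYPE=PROTEIN MISSING=? GAP=-;",
    "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", format(names(seqs)), unname(seqs)), con)
  writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
  writeLines(sprintf("  CHARSET %s = %d-%d;", sm$partitions$gene_id,
                     sm$partitions$start, sm$partitions$end), con)
  writeLines("END;", con)
  invisible(path)
}
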