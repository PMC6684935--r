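#' Gene family container
#'
#' A gene family bundles one locus: its identifier, a member table with one
#' row per candidate sequence (a taxon may carry several candidates before
#' ortholog resolution), and an aligned flag. Aligned families must have
#' equal-length sequences; their common length is stored as
#' `alignment_length`.
#'
#' @param gene_id single gene identifier.
#' @param members tibble or data frame with columns `taxon_id`, `seq_id`,
#'   `sequence` (one row per candidate sequence).
#' @param aligned logical; are the sequences aligned to a common length?
#' @return an object of class `gene_family`.
#' @export
gene_family <- function(gene_id, members, aligned = TRUE) {
  stopifnot(length(gene_id) == 1L)
  members <- as_tibble(members)
  req <- c("taxon_id", "seq_id", "sequence")
  if (!all(req %in% names(members))) {
    abort(paste0("gene family '", gene_id, "': members need columns ",
                 paste(req, collapse = ", ")))
  }
  if (anyDuplicated(members$seq_id)) {
    abort(paste0("gene family '", gene_id, "': duplicated seq_id"))
  }
  alen <- NA_integer_
  if (aligned && nrow(members) > 0L) {
    lens <- unique(nchar(members$sequence))
    if (length(lens) != 1L) {
      abort(paste0("alignment error in gene '", gene_id,
                   "': ragged sequence lengths ",
                   paste(sort(lens), collapse = ", ")))
    }
    alen <- as.integer(lens)
  }
  structure(
    list(gene_id = as.character(gene_id), members = members,
         aligned = isTRUE(aligned), alignment_length = alen),
    class = "gene_family"
  )
}

#' @export
print.gene_family <- function(x, ...) {
  cat("<gene_family> ", x$gene_id, ": ", nrow(x$members), " sequences, ",
      length(unique(x$members$taxon_id)), " taxa",
      if (x$aligned) paste0(", aligned (", x$alignment_length, " cols)"),
      "\n", sep = "")
  invisible(x)
}

# one sequence per taxon, as a named character vector (names = taxon_id)
gf_taxon_seqs <- function(gf) {
  m <- gf$members
  if (anyDuplicated(m$taxon_id)) {
    abort(paste0("gene family '", gf$gene_id,
                 "': more than one sequence per taxon; resolve candidates first"))
  }
  setNames(m$sequence, m$taxon_id)
}

#' Convert sequences to an alignment character matrix
#'
#' Rows are taxa (or sequence ids), columns are alignment positions, each
#' cell a single uppercase character.
#'
#' @param x named character vector of equal-length strings, a `gene_family`
#'   (one sequence per taxon), or an existing character matrix.
#' @return character matrix with rownames.
#' @export
as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "character"
    return(x)
  }
  if (inherits(x, "gene_family")) x <- gf_taxon_seqs(x)
  if (inherits(x, "supermatrix")) return(x$matrix)
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("sequences must be named")
  }
  lens <- unique(nchar(x))
  if (length(lens) > 1L) abort("sequences have unequal lengths; not aligned")
  if (length(x) == 0L || lens == 0L) {
    return(matrix(character(0), nrow = length(x), ncol = 0,
                  dimnames = list(names(x), NULL)))
  }
  m <- do.call(rbind, strsplit(toupper(unname(x)), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

# matrix -> named character vector of strings
alignment_strings <- function(m) {
  if (ncol(m) == 0L) return(setNames(rep("", nrow(m)), rownames(m)))
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings readers/writers returning plain named
#' character vectors, the package's working currency for sequences.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param width line width for wrapping on output.
#' @return `read_fasta()` a named character vector; `write_fasta()` the path,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read and write relaxed PHYLIP alignments
#'
#' Relaxed PHYLIP: a header line `ntaxa ncolumns`, then one record per taxon
#' of `name  sequence` with whitespace-separated fields and no 10-character
#' name limit. Sequential (non-interleaved) layout; any single-character
#' state alphabet is preserved, so recoded 6-state matrices round-trip.
#'
#' @param path file path.
#' @param seqs named character vector of equal-length sequences.
#' @return `read_phylip()` a named character vector; `write_phylip()` the
#'   path, invisibly.
#' @export
read_phylip <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  ntax <- as.integer(hdr[1L]); ncol <- as.integer(hdr[2L])
  body <- lines[-1L]
  if (length(body) != ntax) {
    abort(paste0("phylip parse error in ", path, ": expected ", ntax,
                 " records, found ", length(body)))
  }
  parts <- strsplit(trimws(body), "\\s+")
  nm <- map_chr(parts, 1L)
  sq <- map_chr(parts, function(p) paste(p[-1L], collapse = ""))
  if (any(nchar(sq) != ncol)) {
    abort(paste0("phylip parse error in ", path, ": sequence length != ", ncol))
  }
  setNames(sq, nm)
}

#' @rdname read_phylip
#' @export
write_phylip <- function(seqs, path) {
  lens <- unique(nchar(seqs))
  if (length(seqs) > 0L && length(lens) != 1L) abort("unequal sequence lengths")
  ncol <- if (length(seqs)) lens else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(seqs), ncol), con)
  if (length(seqs)) {
    writeLines(paste(format(names(seqs), width = max(nchar(names(seqs))) + 2L),
                     unname(seqs)), con)
  }
  invisible(path)
}
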