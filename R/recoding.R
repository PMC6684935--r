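#' Amino-acid recoding schemes
#'
#' A recoding scheme partitions the 20 canonical amino acids into disjoint
#' classes and maps each residue to its class symbol; missing-data and
#' ambiguity symbols pass through as `'?'` (gaps stay `'-'`). [dayhoff6()]
#' is the standard six-class scheme grouping residues by chemical and
#' physical properties — \{A,G,P,S,T\}, \{D,E,N,Q\}, \{H,K,R\}, \{F,W,Y\},
#' \{I,L,M,V\}, \{C\} — written with class symbols '0'..'5' so recoded
#' states cannot collide with residue letters. Recoding is idempotent:
#' class symbols map to themselves.
#'
#' @param name scheme name.
#' @param groups list of character vectors partitioning the 20 amino acids.
#' @param output_symbols one distinct single character per group.
#' @param passthrough symbols mapped to `'?'` (besides `'-'`, kept as is).
#' @return an object of class `recoding_scheme`.
#' @export
recoding_scheme <- function(name, groups, output_symbols,
                            passthrough = c("?", "X", "*", "B", "Z", "J",
                                            "U", "O")) {
  aa <- sort(unlist(groups))
  canon <- sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
  if (!identical(aa, canon)) {
    abort(paste0("scheme '", name, "': groups must partition the 20 canonical",
                 " amino acids exactly"))
  }
  if (length(output_symbols) != length(groups) ||
        anyDuplicated(output_symbols)) {
    abort("need one distinct output symbol per group")
  }
  map <- character(0)
  for (i in seq_along(groups)) {
    map[groups[[i]]] <- output_symbols[i]
    map[output_symbols[i]] <- output_symbols[i]  # idempotence
  }
  map[passthrough] <- "?"
  map["-"] <- "-"
  structure(list(name = name, groups = groups,
                 output_symbols = output_symbols, map = map),
            class = "recoding_scheme")
}

#' @rdname recoding_scheme
#' @export
dayhoff6 <- function() {
  recoding_scheme(
    "dayhoff6",
    groups = list(c("A", "G", "P", "S", "T"),
                  c("D", "E", "N", "Q"),
                  c("H", "K", "R"),
                  c("F", "W", "Y"),
                  c("I", "L", "M", "V"),
                  "C"),
    output_symbols = as.character(0:5)
  )
}

#' Load a recoding scheme from a config block
#'
#' Reads a YAML block of the form `name`, `groups` (list of strings, one per
#' class) and optional `symbols`, so alternative six-state schemes (S&R-6,
#' KGB-6) can be supplied as data.
#'
#' @param x a file path or a pre-parsed list.
#' @return a [recoding_scheme()].
#' @export
read_recoding_scheme <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  groups <- map(x$groups, function(g) strsplit(toupper(g), "")[[1L]])
  symbols <- x$symbols %||% as.character(seq_along(groups) - 1L)
  recoding_scheme(x$name %||% "custom", groups, as.character(symbols))
}

#' Recode an alignment
#'
#' Replaces every residue by its class symbol under `scheme`. Dimensions,
#' taxon order, partitions and the missing-cell mask are unchanged.
#'
#' @param x a `supermatrix`, aligned [gene_family()], character matrix, or
#'   named character vector of aligned sequences.
#' @param scheme a [recoding_scheme()]; default [dayhoff6()].
#' @return object of the same shape as `x` (gene families come back as
#'   gene families, supermatrices as supermatrices, otherwise a character
#'   matrix).
#' @export
recode <- function(x, scheme = dayhoff6()) {
  stopifnot(inherits(scheme, "recoding_scheme"))
  if (inherits(x, "supermatrix")) {
    return(new_supermatrix(recode_matrix(x$matrix, scheme), x$partitions))
  }
  if (inherits(x, "gene_family")) {
    m <- recode_matrix(as_alignment_matrix_members(x), scheme)
    members <- mutate(x$members, sequence = unname(alignment_strings(m)))
    return(gene_family(x$gene_id, members, aligned = x$aligned))
  }
  recode_matrix(as_alignment_matrix(x), scheme)
}

# member-level matrix (rows = seq_id), for families with multiple candidates
as_alignment_matrix_members <- function(gf) {
  as_alignment_matrix(setNames(gf$members$sequence, gf$members$seq_id))
}

recode_matrix <- function(m, scheme) {
  if (length(m) == 0L) return(m)
  out <- scheme$map[m]
  if (anyNA(out)) {
    bad <- which(is.na(matrix(out, nrow(m))), arr.ind = TRUE)[1L, ]
    abort(paste0("data error: unknown symbol '", m[bad[1L], bad[2L]],
                 "' at taxon '", rownames(m)[bad[1L]], "', column ",
                 bad[2L]))
  }
  matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Check that recoding cannot inflate pairwise distances
#'
#' Recoding only merges residue states, so for every taxon pair the
#' uncorrected p-distance after recoding is at most the p-distance before.
#' This emits that comparison as a checkable per-pair report.
#'
#' @param x an aligned `supermatrix`, [gene_family()] or character matrix.
#' @param scheme a [recoding_scheme()].
#' @return tibble taxon_a, taxon_b, p_before, p_after, ok.
#' @export
recoded_p_distance_leq <- function(x, scheme = dayhoff6()) {
  before <- p_distance_matrix(x)
  after <- p_distance_matrix(recode(x, scheme))
  taxa <- rownames(before)
  pairs <- which(upper.tri(before), arr.ind = TRUE)
  tibble(
    taxon_a = taxa[pairs[, 1L]], taxon_b = taxa[pairs[, 2L]],
    p_before = before[pairs], p_after = after[pairs],
    ok = is.na(before[pairs]) | is.na(after[pairs]) |
      after[pairs] <= before[pairs] + 1e-12
  )
}
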