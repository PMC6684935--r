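#' Uncorrected pairwise distance matrix
#'
#' For each taxon pair, the proportion of differing sites among columns where
#' both taxa carry data (pairwise deletion). Pairs with zero comparable
#' columns are undefined and returned as `NA`; they are excluded from any
#' downstream regression.
#'
#' @param x an aligned `supermatrix`, [gene_family()], character matrix or
#'   named character vector.
#' @param missing_chars symbols treated as missing.
#' @return square symmetric numeric matrix with zero diagonal and attribute
#'   `kind = "uncorrected_p"`.
#' @export
p_distance_matrix <- function(x, missing_chars = MISSING_CHARS) {
  m <- as_alignment_matrix(x)
  n <- nrow(m)
  if (n < 2L) abort("data error: need at least 2 taxa for distances")
  ok <- matrix(!(m %in% missing_chars), n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <- if (nc == 0L) NA_real_ else
        sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  attr(d, "kind") <- "uncorrected_p"
  d
}

#' Patristic distance matrix
#'
#' Tip-to-tip path-length distances (sums of branch lengths), independent of
#' root placement.
#'
#' @param tree an `ape::phylo` with branch lengths on every edge.
#' @return square symmetric numeric matrix with attribute
#'   `kind = "patristic"`, rows/columns in tip-label order.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all edges" else
      paste("edge", which(is.na(tree$edge.length))[1L])
    abort(paste0("data error: missing branch length (", bad, ")"))
  }
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  attr(d, "kind") <- "patristic"
  d
}

#' Distance matrix in long (pairwise) form
#'
#' @param d square distance matrix with dimnames.
#' @param value name of the value column.
#' @return tibble taxon_a, taxon_b, value (upper triangle only).
#' @export
dist_pairs <- function(d, value = "distance") {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- tibble(taxon_a = rownames(d)[idx[, 1L]],
                taxon_b = colnames(d)[idx[, 2L]])
  out[[value]] <- d[idx]
  out
}

#' Saturation analysis: regress observed on patristic distances
#'
#' Quantifies substitution saturation of an alignment relative to a tree
#' inferred under a substitution model: uncorrected p-distances
#' underestimate divergence more strongly as sites saturate, so they
#' correlate increasingly poorly with model-based (patristic) distances. The
#' statistic is the R-squared of the ordinary least-squares fit of observed
#' on patristic distances over all defined taxon pairs — the lower the
#' R-squared, the greater the saturation.
#'
#' @param observed uncorrected distance matrix (see [p_distance_matrix()]).
#' @param patristic patristic distance matrix (see [patristic_matrix()]).
#'   Taxon sets are intersected with a warning when unequal.
#' @return object of class `saturation_fit` with fields `pairs` (tibble
#'   taxon_a, taxon_b, observed, patristic), `pairs_used`, `slope`,
#'   `intercept`, `r_squared` and the underlying `lm` fit. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
saturation_fit <- function(observed, patristic) {
  shared <- intersect(rownames(observed), rownames(patristic))
  if (!setequal(rownames(observed), rownames(patristic))) {
    warn(paste0("taxon sets differ; using the ", length(shared),
                " shared taxa"))
  }
  if (length(shared) < 3L) abort("statistical error: fewer than 3 shared taxa")
  shared <- sort(shared)
  obs <- observed[shared, shared]
  pat <- patristic[shared, shared]
  pairs <- dist_pairs(obs, "observed")
  pairs$patristic <- dist_pairs(pat, "patristic")$patristic
  pairs <- pairs[!is.na(pairs$observed) & !is.na(pairs$patristic), ]
  if (nrow(pairs) < 3L) {
    abort("statistical error: fewer than 3 defined taxon pairs")
  }
  fit <- lm(observed ~ patristic, data = pairs)
  structure(list(
    pairs = pairs,
    pairs_used = nrow(pairs),
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    # identical to the OLS R^2 for a simple linear regression, and what the
    # saturation index is defined as
    r_squared = stats::cor(pairs$observed, pairs$patristic)^2,
    fit = fit
  ), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit> ", x$pairs_used, " taxon pairs; R^2 = ",
      sprintf("%.3f", x$r_squared), " (slope ", sprintf("%.3f", x$slope),
      ", intercept ", sprintf("%.3f", x$intercept), ")\n", sep = "")
  invisible(x)
}

#' @rdname saturation_fit
#' @param x a `saturation_fit`.
#' @param ... unused.
#' @method tidy saturation_fit
#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(term = c("intercept", "patristic"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname saturation_fit
#' @method glance saturation_fit
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, pairs_used = x$pairs_used)
}

#' @rdname saturation_fit
#' @param object a `saturation_fit`.
#' @method autoplot saturation_fit
#' @export
autoplot.saturation_fit <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$patristic, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "patristic distance (substitutions/site)",
      y = "uncorrected p-distance",
      title = sprintf("Saturation plot (R² = %.2f, %d pairs)",
                      object$r_squared, object$pairs_used)
    ) +
    ggplot2::theme_minimal()
}

# canonical non-trivial splits of an unrooted tree, encoded as sorted tip
# strings of the side not containing the reference tip
tree_splits <- function(tree, ref_taxa) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(ref_taxa)
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (ref_taxa[1L] %in% side) side <- setdiff(ref_taxa, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

split_frequencies <- function(trees, ref_taxa) {
  tab <- table(unlist(map(trees, tree_splits, ref_taxa = ref_taxa)))
  setNames(as.numeric(tab) / length(trees), names(tab))
}

#' Maximum bipartition frequency difference between tree samples
#'
#' The convergence diagnostic for two independent posterior samples of
#' trees: every internal edge of an unrooted tree induces a bipartition
#' (split) of the taxa; each sample assigns each split a frequency (the
#' fraction of its trees containing it), and the statistic is the maximum
#' absolute frequency difference over all non-trivial splits observed in
#' either sample. 0 means the samples agree on every split frequency; 1
#' means some split is fixed in one sample and absent from the other.
#'
#' @param sample_a,sample_b non-empty lists of `phylo` objects (or
#'   `multiPhylo`) on the same tip set.
#' @return the statistic, a number in \[0, 1\].
#' @export
bipartition_maxdiff <- function(sample_a, sample_b) {
  sample_a <- as_tree_list(sample_a)
  sample_b <- as_tree_list(sample_b)
  if (!length(sample_a) || !length(sample_b)) {
    abort("both tree samples must be non-empty")
  }
  taxa <- sort(sample_a[[1L]]$tip.label)
  for (tr in c(sample_a, sample_b)) {
    if (!setequal(tr$tip.label, taxa) ||
          length(tr$tip.label) != length(taxa)) {
      abort("labeling error: tree samples must share an identical tip set")
    }
  }
  fa <- split_frequencies(sample_a, taxa)
  fb <- split_frequencies(sample_b, taxa)
  splits <- union(names(fa), names(fb))
  if (!length(splits)) return(0)
  va <- ifelse(splits %in% names(fa), fa[splits], 0)
  vb <- ifelse(splits %in% names(fb), fb[splits], 0)
  max(abs(va - vb))
}

as_tree_list <- function(x) {
  if (inherits(x, "phylo")) return(list(x))
  if (inherits(x, "multiPhylo")) return(unclass(x))
  x
}
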