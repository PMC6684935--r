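#' Long-branch flagging policy
#'
#' Rule for calling a tip of a gene tree a "long branch": a tip is flagged
#' when its statistic (terminal branch length, or root-to-tip path length)
#' exceeds `multiplier` times a robust center (median by default) of that
#' statistic over all tips. Trees with fewer than `min_tips` tips are skipped
#' with a warning and yield no flags.
#'
#' @param statistic `"terminal_branch"` or `"root_to_tip"`.
#' @param multiplier flag threshold as a multiple of the center (> 1).
#' @param center `"median"` (default) or `"mean"`.
#' @param min_tips minimum usable tree size (>= 3).
#' @return an object of class `long_branch_policy`.
#' @export
long_branch_policy <- function(statistic = c("terminal_branch", "root_to_tip"),
                               multiplier = 4, center = c("median", "mean"),
                               min_tips = 4L) {
  if (multiplier <= 1) abort("multiplier must be > 1")
  if (min_tips < 3L) abort("min_tips must be >= 3")
  structure(list(statistic = match.arg(statistic),
                 multiplier = multiplier,
                 center = match.arg(center),
                 min_tips = as.integer(min_tips)),
            class = "long_branch_policy")
}

tip_statistic <- function(tree, statistic) {
  ntip <- length(tree$tip.label)
  if (statistic == "terminal_branch") {
    stat <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2L])]
  } else {
    stat <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  }
  setNames(stat, tree$tip.label)
}

#' Flag long-branch tips of a gene tree
#'
#' Returns the tips whose branch statistic exceeds the policy threshold
#' (strictly). Deterministic and invariant to tip ordering in the Newick
#' string.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param policy a [long_branch_policy()].
#' @return character vector of flagged tip labels (possibly empty).
#' @seealso [long_branch_report()] for the per-tip statistics behind the
#'   decision.
#' @export
flag_long_branches <- function(tree, policy = long_branch_policy()) {
  rep <- long_branch_report(tree, policy)
  rep$tip[rep$flagged]
}

#' @rdname flag_long_branches
#' @param gene_id optional id prepended as a column, for per-gene reports.
#' @return `long_branch_report()`: tibble with tip, statistic, center,
#'   threshold, flagged.
#' @export
long_branch_report <- function(tree, policy = long_branch_policy(),
                               gene_id = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
        any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    abort("data error: tree branch lengths missing, non-finite or negative")
  }
  ntip <- length(tree$tip.label)
  if (ntip < policy$min_tips) {
    warn(paste0("tree has ", ntip, " tips (< min_tips = ", policy$min_tips,
                "); long-branch screening skipped"))
    out <- tibble(tip = character(0), statistic = numeric(0),
                  center = numeric(0), threshold = numeric(0),
                  flagged = logical(0))
  } else {
    stat <- tip_statistic(tree, policy$statistic)
    ctr <- if (policy$center == "median") median(stat) else mean(stat)
    thr <- policy$multiplier * ctr
    out <- tibble(tip = names(stat), statistic = unname(stat),
                  center = ctr, threshold = thr,
                  flagged = unname(stat) > thr)
  }
  if (!is.null(gene_id)) out <- mutate(out, gene_id = gene_id, .before = 1L)
  out
}

#' Prune tips from a tree
#'
#' Removes the listed tips; resulting degree-2 nodes are suppressed with
#' their branch lengths summed, so patristic distances among the remaining
#' tips are preserved.
#'
#' @param tree an `ape::phylo`.
#' @param tips tip labels to remove (must all exist; may be empty).
#' @return the pruned `phylo`.
#' @export
prune_tips <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("labeling error: unknown tips: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!length(tips)) return(tree)
  if (length(tree$tip.label) - length(tips) < 2L) {
    abort("pruning would leave fewer than 2 tips")
  }
  ape::drop.tip(tree, tips, collapse.singles = TRUE)
}
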