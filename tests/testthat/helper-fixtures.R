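# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

# the default-condition dataset (20 taxa, 200 genes) used by the recovery
# and acceptance tests; memoised because simulation takes a few seconds
default_dataset <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- simulate_dataset(sim_config(seed = 1))
  }
  .fixtures$default
}

small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_dataset(sim_config(n_taxa = 8, n_genes = 12,
                                                   seed = 2))
  }
  .fixtures$small
}

# gene families restricted to the true orthologs (one sequence per taxon)
ortholog_families <- function(ds) {
  lapply(ds$gene_families, function(g) {
    gene_family(g$gene_id,
                g$members[grepl("_o$", g$members$seq_id), , drop = FALSE])
  })
}

pooled_hits <- function(ds) {
  dplyr::bind_rows(purrr::imap(ds$hit_tables,
                               function(h, g) as_hit_table(h, gene_id = g)))
}

all_gene_tree_flags <- function(ds, policy = long_branch_policy()) {
  unlist(purrr::imap(ds$gene_trees, function(tr, g) {
    suppressWarnings(flag_long_branches(tr, policy))
  }), use.names = FALSE)
}

# random aligned family over an alphabet, for property tests
random_alignment <- function(n_taxa, n_cols, alphabet, missing_rate = 0) {
  m <- matrix(sample(alphabet, n_taxa * n_cols, replace = TRUE), n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_taxa)), NULL))
  if (missing_rate > 0) {
    miss <- runif(length(m)) < missing_rate
    m[miss] <- sample(c("?", "-", "X"), sum(miss), replace = TRUE)
  }
  m
}

random_gene_family <- function(gene_id, taxa, n_cols,
                               alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                   "")[[1]],
                               missing_rate = 0.1) {
  m <- random_alignment(length(taxa), n_cols, alphabet, missing_rate)
  rownames(m) <- taxa
  gene_family(gene_id, tibble::tibble(
    taxon_id = taxa, seq_id = paste0(taxa, "_", gene_id),
    sequence = apply(m, 1, paste, collapse = "")))
}

# independent patristic oracle: shortest paths over the tree's edge graph
patristic_oracle <- function(tree) {
  skip_if_not_installed("igraph")
  n_nodes <- length(tree$tip.label) + tree$Nnode
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n_nodes)))
  d <- igraph::distances(g, weights = tree$edge.length)
  tips <- seq_along(tree$tip.label)
  out <- d[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out[order(rownames(out)), order(colnames(out))]
}

# independent split-presence oracle: a subset S is a split of the unrooted
# tree iff S is monophyletic once the tree is rooted at a tip outside S
split_in_tree_oracle <- function(tree, side) {
  out <- setdiff(tree$tip.label, side)
  rooted <- ape::root(tree, outgroup = out[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, side)
}

# brute-force maxdiff: enumerate every canonical non-trivial subset
maxdiff_oracle <- function(sample_a, sample_b) {
  taxa <- sort(sample_a[[1]]$tip.label)
  n <- length(taxa)
  rest <- taxa[-1]
  diffs <- 0
  for (k in 2:(n - 2)) {
    sets <- utils::combn(rest, k, simplify = FALSE)
    for (s in sets) {
      fa <- mean(vapply(sample_a, split_in_tree_oracle, logical(1), side = s))
      fb <- mean(vapply(sample_b, split_in_tree_oracle, logical(1), side = s))
      diffs <- max(diffs, abs(fa - fb))
    }
  }
  diffs
}
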