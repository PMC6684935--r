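# Root-to-tip depth of the simulated species tree, in expected
# substitutions/site at rate multiplier 1. Chosen so the slowest rate class
# stays far from saturation while the fastest (4x) approaches it.
SPECIES_TREE_DEPTH <- 0.5
# Extra divergence (subs/site at rate 1) added to a decoy paralog beyond the
# height of its duplication node, so paralogs are recognisably worse hits.
PARALOG_EXTRA_DEPTH <- 1.0
# log10 e-value model: log10(E) = EVALUE_INTERCEPT - EVALUE_SLOPE * S + noise,
# with S = (percent identity/100) * alignment length; noise sd in log10 units.
EVALUE_INTERCEPT <- 3
EVALUE_SLOPE <- 0.7
EVALUE_LOG10_SD <- 0.5
EVALUE_LOG10_FLOOR <- -180

#' Simulation configuration
#'
#' Parameters of the synthetic gene-family generator. Defaults describe the
#' standard study conditions used throughout the package's tests: 20 taxa,
#' 200 genes, four gene-rate classes spanning an 8-fold range (creating a
#' saturation gradient), 25% per-taxon dropout per gene (targeting ~75%
#' supermatrix completeness), decoy paralogs for 10% of taxon slots, and 5%
#' of tips evolved on an 8-fold elongated terminal branch.
#'
#' @param n_taxa number of taxa in the species tree (>= 4).
#' @param n_genes number of gene families (>= 1).
#' @param gene_length_range min and max protein length in residues.
#' @param rate_classes per-gene rate multipliers sampled uniformly per gene.
#' @param missing_fraction probability a taxon is absent from a gene, in
#'   \[0,1).
#' @param paralog_fraction probability a present taxon gains a decoy paralog.
#' @param long_branch_fraction probability a tip evolves on an elongated
#'   terminal branch.
#' @param long_branch_multiplier terminal-branch elongation factor (> 1).
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20L, n_genes = 200L,
                       gene_length_range = c(100L, 300L),
                       rate_classes = c(0.5, 1, 2, 4),
                       missing_fraction = 0.25,
                       paralog_fraction = 0.1,
                       long_branch_fraction = 0.05,
                       long_branch_multiplier = 8,
                       seed = 1L) {
  cfg <- list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              rate_classes = as.numeric(rate_classes),
              missing_fraction = missing_fraction,
              paralog_fraction = paralog_fraction,
              long_branch_fraction = long_branch_fraction,
              long_branch_multiplier = long_branch_multiplier,
              seed = as.integer(seed))
  chk <- function(ok, field, why) {
    if (!ok) abort(paste0("invalid simulation config: '", field, "' ", why))
  }
  chk(cfg$n_taxa >= 4L, "n_taxa", "must be >= 4")
  chk(cfg$n_genes >= 1L, "n_genes", "must be >= 1")
  chk(length(cfg$gene_length_range) == 2L &&
        all(cfg$gene_length_range > 0L) &&
        cfg$gene_length_range[1L] <= cfg$gene_length_range[2L],
      "gene_length_range", "must be positive (min, max)")
  chk(length(cfg$rate_classes) >= 1L && all(cfg$rate_classes > 0),
      "rate_classes", "must be positive multipliers")
  for (f in c("missing_fraction", "paralog_fraction", "long_branch_fraction")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] < 1, f,
        "must lie in [0, 1)")
  }
  chk(cfg$long_branch_multiplier > 1, "long_branch_multiplier", "must be > 1")
  chk(!is.na(cfg$seed), "seed", "must be an integer")
  structure(cfg, class = "sim_config")
}

# evolve a sequence (character vector of residues) along one branch of length
# b under WAG, reusing the tree simulator on a two-tip tree
sim_branch <- function(seq, b) {
  tr <- ape::read.tree(text = sprintf("(anc:0,derived:%.10f);", b))
  sim <- phangorn::simSeq(tr, l = length(seq), type = "AA", model = "WAG",
                          rootseq = seq)
  as.character(sim)["derived", ]
}

# map percent identity and hit length to a BLAST-like e-value with lognormal
# noise; monotone decreasing in identity * length up to the noise
synth_evalue <- function(pident, len) {
  log10e <- EVALUE_INTERCEPT - EVALUE_SLOPE * (pident / 100) * len +
    rnorm(length(pident), 0, EVALUE_LOG10_SD)
  log10e <- pmin(pmax(log10e, EVALUE_LOG10_FLOOR), 1)
  10^log10e
}

taxon_from_seq_id <- function(seq_id) sub("_g.*$", "", seq_id)

#' Simulate a synthetic phylogenomic dataset
#'
#' Evolves protein gene families along a common ultrametric species tree
#' under the WAG substitution model, scaled per gene by a rate-class
#' multiplier. Each gene independently loses taxa, may gain decoy paralogs
#' (duplicated at a random internal node and evolved further, so their
#' homology-hit e-values are stochastically worse than the true ortholog's),
#' and may carry long-branch tips whose terminal branch is elongated. Per
#' gene a 12-column BLAST-tabular hit table is synthesised against the gene's
#' ancestral (root) sequence, with e-values a monotone noisy function of
#' identity times length.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_dataset` with elements `species_tree`
#'   (`ape::phylo`), `gene_families` (named list of [gene_family()]),
#'   `gene_trees` (named list of `phylo`, tips labelled by sequence id),
#'   `hit_tables` (named list of tibbles), `truth` (tibble: gene_id, seq_id,
#'   taxon_id, role, long_branch), `genes` (tibble of per-gene rate class and
#'   length) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  taxa <- sprintf("t%02d", seq_len(config$n_taxa))
  # random topology; branch lengths uniform within a 3-fold range (moderate
  # lineage rate heterogeneity), rescaled to a mean root-to-tip depth of
  # SPECIES_TREE_DEPTH substitutions/site at rate multiplier 1
  stree <- ape::rtree(config$n_taxa, tip.label = taxa, br = NULL)
  stree$edge.length <- runif(nrow(stree$edge), 0.5, 1.5)
  depths <- ape::node.depth.edgelength(stree)
  stree$edge.length <- stree$edge.length *
    (SPECIES_TREE_DEPTH / mean(depths[seq_len(config$n_taxa)]))

  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  rate_idx <- sample.int(length(config$rate_classes), config$n_genes,
                         replace = TRUE)
  lens <- sample(seq(config$gene_length_range[1L],
                     config$gene_length_range[2L]),
                 config$n_genes, replace = TRUE)

  depths <- ape::node.depth.edgelength(stree)  # distance from root, all nodes
  ntip <- length(taxa)
  internal_nodes <- (ntip + 1L):(ntip + stree$Nnode)

  families <- vector("list", config$n_genes)
  gtrees <- vector("list", config$n_genes)
  hits <- vector("list", config$n_genes)
  truths <- vector("list", config$n_genes)

  for (i in seq_len(config$n_genes)) {
    g <- gene_ids[i]
    rate <- config$rate_classes[rate_idx[i]]
    len <- lens[i]

    gt <- stree
    gt$edge.length <- gt$edge.length * rate
    lb_tips <- taxa[runif(ntip) < config$long_branch_fraction]
    if (length(lb_tips)) {
      term <- match(match(lb_tips, gt$tip.label), gt$edge[, 2L])
      gt$edge.length[term] <- gt$edge.length[term] *
        config$long_branch_multiplier
    }

    sim <- phangorn::simSeq(gt, l = len, type = "AA", model = "WAG",
                            ancestral = TRUE)
    chars <- as.character(sim)  # rows: tips then internal nodes (by number)
    rootseq <- chars[as.character(ntip + 1L), ]

    keep <- taxa[runif(ntip) >= config$missing_fraction]
    if (length(keep) < 3L) keep <- sample(taxa, 3L)  # a usable family needs >= 3 taxa

    ort_ids <- setNames(paste0(keep, "_", g, "_o"), keep)
    seqs <- map_chr(keep, function(tx) paste(chars[tx, ], collapse = ""))

    # decoy paralogs: duplicate at a random internal node, evolve further
    par_tab <- NULL
    otree <- gt
    otree$node.label <- NULL
    par_taxa <- keep[runif(length(keep)) < config$paralog_fraction]
    for (tx in par_taxa) {
      v <- sample(internal_nodes, 1L)
      v_desc <- unlist(phangorn::Descendants(stree, v, type = "tips"))
      height_v <- mean(depths[v_desc]) - depths[v]  # mean node-to-tip depth
      b_par <- rate * (height_v + PARALOG_EXTRA_DEPTH)
      pseq <- sim_branch(chars[as.character(v), ], b_par)
      pid <- paste0(tx, "_", g, "_p")
      par_tab <- bind_rows(par_tab, tibble(
        taxon_id = tx, seq_id = pid,
        sequence = paste(pseq, collapse = "")))
      # relocate v after earlier grafts via the MRCA of its original tips
      v_tips <- gt$tip.label[unlist(phangorn::Descendants(gt, v, type = "tips"))]
      where <- if (length(v_tips) == ntip) length(otree$tip.label) +
        1L else ape::getMRCA(otree, v_tips)
      otree <- phytools::bind.tip(otree, pid, edge.length = b_par,
                                  where = where)
    }

    members <- tibble(taxon_id = keep, seq_id = unname(ort_ids),
                      sequence = seqs)
    if (!is.null(par_tab)) members <- bind_rows(members, par_tab)
    families[[i]] <- gene_family(g, members, aligned = TRUE)

    # output gene tree: rename ortholog tips to seq ids, drop missing taxa
    otree$tip.label <- ifelse(otree$tip.label %in% keep,
                              paste0(otree$tip.label, "_", g, "_o"),
                              otree$tip.label)
    drop <- setdiff(taxa, keep)
    if (length(drop)) otree <- ape::drop.tip(otree, drop)
    gtrees[[i]] <- otree

    matches <- map_int(members$sequence, function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1L]] == rootseq)
    })
    pident <- round(100 * matches / len, 2)
    hits[[i]] <- tibble(
      qseqid = paste0(g, "_query"), sseqid = members$seq_id,
      pident = pident, length = len, mismatch = len - matches,
      gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
      evalue = synth_evalue(pident, len),
      bitscore = round(2 * (pident / 100) * len, 1))

    truths[[i]] <- tibble(
      gene_id = g, seq_id = members$seq_id, taxon_id = members$taxon_id,
      role = ifelse(grepl("_o$", members$seq_id), "ortholog", "paralog"),
      long_branch = members$taxon_id %in% lb_tips & grepl("_o$", members$seq_id))
  }

  structure(list(
    species_tree = stree,
    gene_families = setNames(families, gene_ids),
    gene_trees = setNames(gtrees, gene_ids),
    hit_tables = setNames(hits, gene_ids),
    truth = bind_rows(truths),
    genes = tibble(gene_id = gene_ids,
                   rate = config$rate_classes[rate_idx],
                   rate_class = rate_idx, length = lens),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", length(x$gene_families), " gene families, ",
      length(x$species_tree$tip.label), " taxa, seed ", x$config$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes one FASTA and one 12-column BLAST-tabular hit file per gene, all
#' gene trees and the species tree as Newick, the truth and per-gene tables
#' as TSV, and a manifest listing every file written.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param directory output directory (created if absent).
#' @return path of the manifest file, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) abort(paste0("cannot create directory: ", directory))
  for (d in c("genes", "hits", "gene_trees")) {
    dir.create(file.path(directory, d), showWarnings = FALSE)
  }
  files <- character(0)
  for (g in names(dataset$gene_families)) {
    gf <- dataset$gene_families[[g]]
    fa <- file.path("genes", paste0(g, ".fasta"))
    write_fasta(setNames(gf$members$sequence, gf$members$seq_id),
                file.path(directory, fa))
    ht <- file.path("hits", paste0(g, ".tsv"))
    write_hit_table(dataset$hit_tables[[g]], file.path(directory, ht))
    tr <- file.path("gene_trees", paste0(g, ".nwk"))
    ape::write.tree(dataset$gene_trees[[g]], file.path(directory, tr))
    files <- c(files, fa, ht, tr)
  }
  ape::write.tree(dataset$species_tree,
                  file.path(directory, "species_tree.nwk"))
  write_tsv_plain(dataset$truth, file.path(directory, "truth.tsv"))
  write_tsv_plain(dataset$genes, file.path(directory, "genes.tsv"))
  files <- c(files, "species_tree.nwk", "truth.tsv", "genes.tsv")
  manifest <- file.path(directory, "manifest.tsv")
  write_tsv_plain(tibble(file = files), manifest)
  invisible(manifest)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
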