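gf_from_strings <- function(gene_id, seqs) {
  gene_family(gene_id, tibble::tibble(
    taxon_id = names(seqs), seq_id = paste0(names(seqs), "_", gene_id),
    sequence = unname(seqs)))
}

test_that("concatenation pads missing blocks and records partitions", {
  g1 <- gf_from_strings("g1", c(A = strrep("M", 10), B = strrep("K", 10),
                                C = strrep("L", 10)))
  g2 <- gf_from_strings("g2", c(A = strrep("R", 20), B = strrep("D", 20)))
  sm <- concatenate(list(g1, g2))
  expect_identical(dim(sm$matrix), c(3L, 30L))
  expect_identical(rownames(sm$matrix), c("A", "B", "C"))
  expect_identical(sm$partitions$gene_id, c("g1", "g2"))
  expect_identical(sm$partitions$start, c(1L, 11L))
  expect_identical(sm$partitions$end, c(10L, 30L))
  expect_true(all(sm$matrix["C", 11:30] == "?"))
  # completeness 70 data cells of 90
  expect_equal(completeness(sm), 100 * 70 / 90, tolerance = 1e-10)
  # single gene: identity up to the padded representation
  one <- concatenate(list(g1))
  expect_identical(one$matrix, as_alignment_matrix(g1))
  expect_identical(one$partitions$end, 10L)
})

test_that("ragged or duplicated-taxon genes are alignment errors naming the gene", {
  bad <- tibble::tibble(taxon_id = c("A", "B"), seq_id = c("a", "b"),
                        sequence = c("MKL", "MK"))
  expect_error(gene_family("gbad", bad), "gbad")
  dup <- gene_family("gdup", tibble::tibble(
    taxon_id = c("A", "A"), seq_id = c("a1", "a2"),
    sequence = c("MKL", "MKV")))
  expect_error(concatenate(list(dup)), "gdup")
})

test_that("concatenation is associative cell-wise", {
  set.seed(23)
  taxa <- sprintf("t%02d", 1:6)
  gs <- lapply(1:3, function(i) {
    random_gene_family(paste0("g", i), sample(taxa, sample(3:6, 1)),
                       sample(5:15, 1))
  })
  ab_c <- concatenate(list(
    gf_from_strings("ab",
                    alignment_strings(concatenate(gs[1:2])$matrix)),
    gf_from_strings("c", alignment_strings(as_alignment_matrix(gs[[3]])))))
  abc <- concatenate(gs)
  # oracle: direct cell comparison over the shared taxon set
  taxa_all <- rownames(abc$matrix)
  expect_identical(ab_c$matrix[taxa_all, ], abc$matrix[taxa_all, ])
})

test_that("occupancy filter is inclusive at the boundary and monotone", {
  taxa <- c("A", "B", "C", "D")
  g_half <- random_gene_family("half", c("A", "B"), 8, missing_rate = 0)
  g_quarter <- random_gene_family("quarter", "A", 8, missing_rate = 0)
  kept <- occupancy_filter(list(g_half, g_quarter), 0.5, taxa)
  expect_identical(purrr::map_chr(kept, "gene_id"), "half")
  expect_length(occupancy_filter(list(g_half, g_quarter), 0, taxa), 2)
  # monotone: raising the threshold never resurrects a dropped gene
  set.seed(5)
  genes <- lapply(1:10, function(i) {
    random_gene_family(paste0("g", i), sample(taxa, sample(1:4, 1)), 6)
  })
  prev <- genes
  for (thr in c(0.25, 0.5, 0.75, 1)) {
    now <- occupancy_filter(genes, thr, taxa)
    expect_true(all(purrr::map_chr(now, "gene_id") %in%
                      purrr::map_chr(prev, "gene_id")))
    prev <- now
  }
})

test_that("completeness equals the occupancy-weighted per-gene average", {
  set.seed(7)
  taxa <- sprintf("t%02d", 1:8)
  genes <- lapply(1:6, function(i) {
    random_gene_family(paste0("g", i), sample(taxa, sample(4:8, 1)),
                       sample(10:30, 1), missing_rate = 0.15)
  })
  sm <- concatenate(genes)
  n_taxa <- nrow(sm$matrix)
  widths <- sm$partitions$end - sm$partitions$start + 1L
  # per-gene completeness measured over the full taxon set of the matrix
  per_gene <- vapply(seq_along(genes), function(i) {
    completeness(sm$matrix[, sm$partitions$start[i]:sm$partitions$end[i],
                           drop = FALSE])
  }, numeric(1))
  expect_equal(completeness(sm), sum(per_gene * widths) / sum(widths),
               tolerance = 1e-10)
  expect_equal(completeness(matrix("A", 2, 2)), 100)
})

test_that("the 'X counts as data' completeness mode is available", {
  m <- matrix(c("A", "X", "-", "?"), 2, 2)
  expect_equal(completeness(m), 25)
  expect_equal(completeness(m, missing_chars = c("?", "-")), 50)
})

test_that("column filter matches brute-force per-column counting", {
  set.seed(11)
  taxa <- sprintf("t%02d", 1:6)
  genes <- lapply(1:4, function(i) {
    random_gene_family(paste0("g", i), sample(taxa, sample(2:6, 1)),
                       sample(8:20, 1), missing_rate = 0.2)
  })
  sm <- concatenate(genes)
  for (thr in c(0, 0.3, 0.6, 1)) {
    got <- simple_column_filter(sm, thr)
    # oracle: naive per-column recount
    keep <- apply(sm$matrix, 2, function(col) {
      mean(col %in% c("?", "-", "X")) <= thr
    })
    expect_identical(ncol(got$matrix), sum(keep))
    expect_identical(got$matrix, sm$matrix[, keep, drop = FALSE])
    if (nrow(got$partitions) > 0) {
      expect_identical(got$partitions$start[1], 1L)
      expect_identical(got$partitions$end[nrow(got$partitions)],
                       ncol(got$matrix))
    }
  }
  # threshold 1 is the identity; an all-missing column dies at any thr < 1
  expect_identical(simple_column_filter(sm, 1)$matrix, sm$matrix)
  smx <- sm
  smx$matrix[, 3] <- "?"
  expect_false(3L %in% which(apply(simple_column_filter(smx, 0.99)$matrix, 2,
                                   function(c) all(c == "?"))))
})

test_that("supermatrix round-trips through fasta, phylip and nexus", {
  set.seed(13)
  taxa <- sprintf("t%02d", 1:5)
  genes <- lapply(1:3, function(i) {
    random_gene_family(paste0("g", i), sample(taxa, sample(3:5, 1)),
                       sample(6:12, 1), missing_rate = 0.1)
  })
  sm <- concatenate(genes)
  for (fmt in c("fasta", "phylip")) {
    path <- tempfile()
    write_supermatrix(sm, path, format = fmt)
    back <- read_supermatrix(path, format = fmt)
    expect_identical(back$matrix, sm$matrix)
    expect_identical(back$partitions, sm$partitions)
  }
  nx <- tempfile(fileext = ".nex")
  write_supermatrix(sm, nx, format = "nexus")
  lines <- readLines(nx)
  expect_identical(lines[1], "#NEXUS")
  expect_length(grep("^  CHARSET", lines), 3)
  # partition file dialect: "GENE = start-end"
  pp <- tempfile()
  write_partitions(sm$partitions, pp)
  expect_identical(read_partitions(pp), sm$partitions)
})

test_that("occupancy report fractions are consistent with the matrix", {
  ds <- small_dataset()
  sm <- concatenate(ortholog_families(ds))
  occ <- occupancy_report(sm)
  expect_true(all(occ$per_gene$taxon_fraction >= 0 &
                    occ$per_gene$taxon_fraction <= 1))
  expect_true(all(occ$per_taxon$gene_fraction >= 0 &
                    occ$per_taxon$gene_fraction <= 1))
  expect_equal(occ$completeness, completeness(sm))
  expect_identical(nrow(occ$per_gene), nrow(sm$partitions))
  expect_identical(nrow(occ$per_taxon), nrow(sm$matrix))
})
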