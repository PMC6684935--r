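test_that("p-distances follow pairwise-deletion arithmetic", {
  m <- as_alignment_matrix(c(a = "ACDE", b = "ACDF"))
  expect_equal(p_distance_matrix(m)["a", "b"], 0.25)
  m2 <- as_alignment_matrix(c(a = "AC-E", b = "ACDF"))
  expect_equal(p_distance_matrix(m2)["a", "b"], 1 / 3)
  ident <- as_alignment_matrix(c(a = "MKLV", b = "MKLV"))
  expect_equal(p_distance_matrix(ident)["a", "b"], 0)
  # zero comparable columns: undefined, marked NA
  gap <- as_alignment_matrix(c(a = "--AA", b = "CC--"))
  expect_true(is.na(p_distance_matrix(gap)["a", "b"]))
  expect_error(p_distance_matrix(m[1, , drop = FALSE]), "2 taxa")
  # brute-force per-column oracle on random alignments
  set.seed(3)
  m3 <- random_alignment(5, 30, c("A", "C", "D", "E"), missing_rate = 0.2)
  d <- p_distance_matrix(m3)
  for (i in 1:4) for (j in (i + 1):5) {
    diffs <- 0; comp <- 0
    for (k in 1:30) {
      x <- m3[i, k]; y <- m3[j, k]
      if (!x %in% c("?", "-", "X") && !y %in% c("?", "-", "X")) {
        comp <- comp + 1
        if (x != y) diffs <- diffs + 1
      }
    }
    expect_equal(d[i, j], if (comp == 0) NA_real_ else diffs / comp)
  }
})

test_that("patristic distances are path sums, root-invariant, oracle-exact", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  d <- patristic_matrix(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 5)
  expect_equal(d["B", "C"], 6)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "B", resolve.root = TRUE)
  expect_equal(patristic_matrix(rerooted), d, ignore_attr = TRUE)
  # shortest-path oracle on random trees up to 8 tips
  set.seed(19)
  for (i in 1:10) {
    tree <- ape::rtree(sample(4:8, 1))
    expect_equal(patristic_matrix(tree), patristic_oracle(tree),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  noblen <- ape::read.tree(text = "((A,B),C);")
  expect_error(patristic_matrix(noblen), "branch length")
})

test_that("patristic distances satisfy the four-point condition", {
  set.seed(29)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:6, 1))
    d <- patristic_matrix(tr)
    taxa <- rownames(d)
    for (q in utils::combn(taxa, 4, simplify = FALSE)) {
      s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                  d[q[1], q[3]] + d[q[2], q[4]],
                  d[q[1], q[4]] + d[q[2], q[3]]))
      expect_lt(s[3] - s[2], 1e-9)  # two largest sums equal on additive trees
    }
  }
})

test_that("the saturation fit reports OLS slope and squared correlation", {
  # observed exactly proportional to patristic: perfect fit
  tr <- ape::rtree(8)
  pat <- patristic_matrix(tr)
  obs <- pat * 0.42
  attr(obs, "kind") <- "uncorrected_p"
  fit <- saturation_fit(obs, pat)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.42, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$pairs_used, choose(8, 2), ignore_attr = TRUE)
  # r_squared invariant under uniform rescaling of either matrix
  noisy <- obs + matrix(abs(rnorm(64, 0, 0.05)), 8, 8)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  dimnames(noisy) <- dimnames(pat)
  f0 <- saturation_fit(noisy, pat)
  f1 <- saturation_fit(noisy * 3, pat)
  f2 <- saturation_fit(noisy, pat * 10)
  expect_equal(f0$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f0$r_squared, f2$r_squared, tolerance = 1e-12)
  # broom-style accessors
  expect_identical(glance(fit)$pairs_used, fit$pairs_used)
  expect_identical(tidy(fit)$term, c("intercept", "patristic"))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("taxon mismatches warn and shrink to the shared set; tiny sets error", {
  tr <- ape::rtree(6)
  pat <- patristic_matrix(tr)
  obs <- pat * 0.5
  attr(obs, "kind") <- "uncorrected_p"
  obs5 <- obs[-1, -1]
  expect_warning(fit <- saturation_fit(obs5, pat), "shared")
  expect_equal(fit$pairs_used, choose(5, 2), ignore_attr = TRUE)
  expect_error(suppressWarnings(saturation_fit(obs[1:2, 1:2], pat)),
               "statistical error")
})

test_that("undefined pairs are excluded listwise from the fit", {
  tr <- ape::rtree(5)
  pat <- patristic_matrix(tr)
  obs <- pat * 0.3
  obs[1, 2] <- obs[2, 1] <- NA
  attr(obs, "kind") <- "uncorrected_p"
  fit <- saturation_fit(obs, pat)
  expect_equal(fit$pairs_used, choose(5, 2) - 1)
})

test_that("faster-evolving alignments fit worse than slower ones", {
  # same tree, rate x10: the high-rate matrix must be more saturated
  set.seed(37)
  wins <- 0
  for (i in 1:20) {
    tr <- ape::rtree(10)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
    slow <- phangorn::simSeq(tr, l = 300, type = "AA", model = "WAG")
    fast_tr <- tr; fast_tr$edge.length <- tr$edge.length * 10
    fast <- phangorn::simSeq(fast_tr, l = 300, type = "AA", model = "WAG")
    pat <- patristic_matrix(tr)
    r2 <- function(s) {
      m <- toupper(as.character(s))
      saturation_fit(p_distance_matrix(m), pat)$r_squared
    }
    wins <- wins + (r2(slow) > r2(fast))
  }
  expect_gte(wins, 18)
})

test_that("rate class and per-gene saturation R^2 are negatively rank-correlated", {
  # long-branch sequences violate the species-tree distances for reasons
  # unrelated to the gene's rate class, so they are screened out first —
  # exactly what the tree-QC stage exists for
  ds <- default_dataset()
  fams <- ortholog_families(ds)
  pat <- patristic_matrix(ds$species_tree)
  lb <- ds$truth$seq_id[ds$truth$long_branch]
  per_gene <- purrr::map_dbl(ds$genes$gene_id, function(g) {
    gf <- fams[[g]]
    m <- as_alignment_matrix(
      gene_family(g, gf$members[!gf$members$seq_id %in% lb, , drop = FALSE]))
    rownames(m) <- sub("_g.*$", "", rownames(m))
    saturation_fit(suppressWarnings(p_distance_matrix(m)),
                   pat[rownames(m), rownames(m)])$r_squared
  })
  expect_lt(cor(ds$genes$rate, per_gene, method = "spearman"), -0.3)
})

test_that("bipartition maxdiff is exact on hand cases and matches enumeration", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_equal(bipartition_maxdiff(list(t1), list(t1)), 0)
  expect_equal(bipartition_maxdiff(list(t1), list(t2)), 1)
  # 5-tip samples of 4 trees each vs brute-force split enumeration
  set.seed(47)
  for (rep in 1:5) {
    sa <- lapply(1:4, function(i) ape::rtree(5, tip.label = letters[1:5]))
    sb <- lapply(1:4, function(i) ape::rtree(5, tip.label = letters[1:5]))
    got <- bipartition_maxdiff(sa, sb)
    expect_equal(got, maxdiff_oracle(sa, sb), tolerance = 1e-12)
    # symmetry and bounds
    expect_equal(got, bipartition_maxdiff(sb, sa))
    expect_gte(got, 0); expect_lte(got, 1)
  }
  expect_error(bipartition_maxdiff(list(t1),
                                   list(ape::rtree(5, tip.label = LETTERS[1:5]))),
               "labeling")
  expect_error(bipartition_maxdiff(list(), list(t1)), "non-empty")
})

test_that("distance matrices export to long pairwise form", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  pairs <- dist_pairs(patristic_matrix(tr), "patristic")
  expect_identical(nrow(pairs), 3L)
  expect_setequal(pairs$patristic, c(3, 5, 6))
})
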