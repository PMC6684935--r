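---
title: "Supermatrix assembly and saturation diagnostics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supermatrix assembly and saturation diagnostics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supersat)
```

## The problem

Phylogenomic supermatrices are assembled by pulling putative orthologs out
of many per-species sequence collections (typically translated
transcriptomes), aligning them gene by gene, and concatenating the gene
alignments into one large partitioned matrix. Every step of that assembly
can inject artifacts that later masquerade as phylogenetic signal:
undetected paralogs, fast-evolving sequences that sit on long branches and
attract each other in trees, and substitution saturation that erodes signal
in the fastest genes. `supersat` implements the assembly bookkeeping and the
standard diagnostics for those artifacts as small, composable, testable
functions, plus a seeded simulator so that the whole chain can be validated
against known ground truth.

## Ortholog selection from homology hits

Candidate orthologs per gene come from BLAST-style homology searches of a
query protein against each taxon's sequences, consumed in the 12-column
tabular dialect. Selection applies two rules:

* **Length-dependent e-value ceiling.** A hit is kept only if its e-value
  reaches the ceiling for its protein length: `1e-20` for proteins shorter
  than 150 residues, and the stricter `1e-80` otherwise. Short proteins
  cannot attain extreme e-values, so they get a lenient ceiling; for long
  proteins the strict ceiling suppresses false-positive orthologs. Both
  ceilings and the cutoff are configurable (`selection_config()`). Two
  under-determined details are made explicit and switchable: the ceiling
  tests the *subject* (candidate) length by default, since the rule guards
  against spurious matches to short candidate sequences; and a protein of
  exactly 150 residues uses the strict ceiling (conservative inclusion).
* **Order-of-magnitude window.** Per taxon, the best (minimum e-value) hit
  is kept together with every hit within three orders of magnitude of it
  (`evalue <= best * 10^3`, inclusive), providing alternative orthologs in
  case the best hit is later rejected. The window can also be anchored once
  per gene (`scope = "gene"`); per-taxon anchoring is the default because
  each taxon contributes at most one sequence per gene and alternatives are
  meaningful within that slot. An e-value of exactly zero is below every
  positive value, and a window anchored at zero keeps only other zero hits,
  because orders of magnitude are undefined at zero. Ties break
  deterministically by (e-value, sequence id).

`resolve_orthologs()` then picks, per (gene, taxon), the best-ranked
candidate not flagged as a long branch in the gene tree; slots whose
candidates are all flagged are dropped.

## Long-branch screening

Gene trees are screened for tips whose branch statistic is an outlier:
a tip is flagged when its terminal branch length (default) or root-to-tip
path exceeds `multiplier` (default 4) times the median (default; mean
optional) of that statistic over all tips. The median center makes the rule
robust to the very outliers it hunts. Trees below `min_tips` (default 4)
tips carry too little information for an outlier rule and are skipped with
a warning rather than an error, so sparse genes degrade gracefully. The
screen is single-pass by design: flagged tips are removed once and the
statistic is not re-computed iteratively, matching how such cleaning is
normally run before concatenation. On a perfectly clock-like tree the
root-to-tip statistic is constant across tips, so no tip can be flagged;
the terminal-branch statistic can legitimately flag tips of ultrametric
trees whose coalescences are very uneven, which is why the policy object
keeps both statistics available.

## Concatenation, occupancy and completeness

`concatenate()` builds the supermatrix over the sorted union of taxa,
padding absent taxon-gene blocks with `'?'` and recording each gene's
1-based inclusive column span in a partition table (the RAxML partition
dialect is used on disk). Completeness is the percentage of cells not in
the missing set; by default `{'?', '-', 'X'}` all count as missing, and the
set is an argument because conventions differ on whether unknown residues
(`X`) are data. The occupancy filter retains genes present in at least a
configurable fraction (default 50%, inclusive at the boundary) of the taxon
universe — the usual pre-concatenation filter for de novo orthogroups.
`simple_column_filter()` drops columns above a missing-fraction threshold
and re-spans partitions; it is a transparent stand-in for external
block-based trimmers (Gblocks and kin), whose heuristics it does not
attempt to reproduce.

## Dayhoff six-state recoding

Recoding collapses the 20 amino acids into six biochemical classes —
{A,G,P,S,T}, {D,E,N,Q}, {H,K,R}, {F,W,Y}, {I,L,M,V}, {C} — so that frequent
within-class replacements no longer count as differences, which damps both
saturation and lineage-specific compositional bias. The class table is the
community-standard Dayhoff-6 partition; because published descriptions of
recoding pipelines rarely print their exact table, the scheme is data-driven
(`recoding_scheme()`, `read_recoding_scheme()`) and alternatives such as
S&R-6 or KGB-6 load from a small YAML block. Class symbols are digits
'0'–'5' so recoded states cannot collide with residue letters, and each
class symbol maps to itself, making `recode()` idempotent. Since recoding
only merges states, the uncorrected p-distance of any taxon pair can never
increase; `recoded_p_distance_leq()` emits that check as a per-pair report.

## Saturation analysis

Substitution saturation is diagnosed by comparing two distance estimates
for every taxon pair: the uncorrected p-distance (proportion of differing
sites among pairwise-complete columns) and the patristic distance (path
length) on a tree inferred under a substitution model that corrects for
multiple hits. As saturation grows, p-distances plateau while patristic
distances keep growing, so the linear relation degrades; the saturation
index is the R² of the ordinary least-squares fit of observed on patristic
distances — the lower the R², the more saturated the matrix. Both
regression orientations give the same R² (it is the squared Pearson
correlation), and the statistic is invariant under uniform rescaling of
either axis. Pairs with no comparable sites are undefined and excluded
listwise, with the used-pair count reported. `autoplot()` draws the
standard saturation scatter.

The patristic computation is delegated to `ape` (the field's reference for
tree arithmetic) and cross-checked in the test suite against an independent
shortest-path oracle; the p-distance, the regression wrapper and all
bookkeeping are native to this package.

## Bipartition convergence statistic

Two independent posterior samples of trees have converged on the same
distribution only if they assign similar frequencies to every bipartition
(split) of the taxa. `bipartition_maxdiff()` computes the maximum absolute
split-frequency difference over all non-trivial splits observed in either
sample — 0 for identical samples, 1 when a split is fixed in one sample and
absent from the other. Splits are counted unrooted and canonicalised
against a reference taxon, so root placement and tip order are irrelevant.
Burn-in is the caller's responsibility: samples are assumed post-burn-in.

## The synthetic-data generator

The generator exists so that every stage has ground truth. Its defaults are
the package's standard study conditions and are not tuned per analysis:

* **Species tree**: random topology over 20 taxa; branch lengths drawn
  uniformly within a 3-fold range (moderate lineage rate heterogeneity) and
  rescaled to a mean root-to-tip depth of 0.5 expected substitutions/site.
* **Gene families**: 200 genes of 100–300 residues evolved along the
  species tree under the WAG model (via `phangorn::simSeq`); a simple
  empirical-frequency process is all the downstream stages need, since they
  consume divergence patterns, not model fine structure. Indels are not
  simulated — column bookkeeping is exercised separately with explicit
  missing symbols.
* **Rate classes** 0.5x, 1x, 2x, 4x, sampled per gene, create the
  saturation gradient: at 4x the deepest paths approach 4 expected
  substitutions per site, deep into saturation, while 0.5x stays nearly
  linear.
* **Missing taxa**: each taxon drops out of each gene independently with
  probability 0.25, targeting the ~75% completeness typical of curated
  transcriptomic supermatrices (a floor of three taxa per gene keeps every
  family usable; at default sizes the floor essentially never binds).
* **Decoy paralogs** (10% of present slots) duplicate at a random internal
  node and evolve an extra 1.0 substitutions/site (at rate 1) beyond that
  node's mean depth — emulating anciently duplicated copies whose
  homology-search e-values are recognisably, but stochastically, worse than
  the true ortholog's.
* **Long branches**: 5% of tips per gene evolve on a terminal branch
  elongated 8-fold.
* **E-values** are synthesised from realised identity:
  `log10 E = 3 − 0.7 · (identity · length)` plus Gaussian noise (sd 0.5
  log-units), floored at 1e-180. Only the ordering and the
  order-of-magnitude structure matter downstream, so a monotone noisy map
  is sufficient and keeps the generator transparent.

What the generator does *not* emulate — alignment error, indels,
compositional heterogeneity across lineages, assembly artifacts,
incomplete-lineage sorting in gene trees (gene trees match the species
topology by construction) — bounds what passing tests show: they validate
the selection, screening, bookkeeping and diagnostic computations, not the
biological robustness of any particular empirical matrix.

Because the simulated gene trees equal the species topology, the two
halves of the pruned gene-tree collection agree on every split and the
bipartition statistic between them is 0; that degenerate value is itself a
correctness check.

## Numerical and degenerate-input choices

* Taxon order in supermatrices is lexicographic; all tie-breaks are
  deterministic, and one seed drives every random draw, so identical
  configs reproduce byte-identical outputs (asserted in the tests).
* The e-value window boundary, the occupancy boundary and the e-value
  ceilings are inclusive.
* Sequences of ragged length within a gene are an error naming the gene;
  unknown residue symbols during recoding are an error naming taxon,
  column and symbol; candidates absent from their gene tree are a labeling
  error listing offenders.
* Distance pairs with no comparable columns are `NA`, never 0; a
  saturation fit requires at least 3 defined pairs.
* `prune_tips()` refuses to prune below 2 tips; degree-2 nodes are
  suppressed with branch lengths summed so patristic distances among
  survivors are exactly preserved.

## Problem sizes

The bundled demo config and the test suite run the full pipeline on 10–20
taxa and 20–200 genes; at those sizes every stage completes in seconds and
the end-to-end demo in well under two minutes on a single core, which the
pipeline test asserts. Larger matrices scale linearly in taxa x columns
for concatenation and recoding, and quadratically in taxa for distance
matrices.

## Limitations

* The long-branch rule is an explicit, auditable outlier policy; published
  cleaning scripts defer their numeric criteria to prior work, so no claim
  is made that this policy reproduces any particular script's decisions.
* The column filter is per-column only and is not a substitute for
  block-aware trimmers.
* Saturation fits against a single reference tree; per-sample patristic
  distances from a posterior are not computed.
* Model-corrected distances are out of scope; the diagnostic is exactly
  the uncorrected-vs-patristic contrast.
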