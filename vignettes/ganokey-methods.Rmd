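---
title: "Methods: identification, morphometrics and barcode-locus scoring for US laccate Ganoderma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identification, morphometrics and barcode-locus scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ganokey)
```

## Scope and data model

`ganokey` implements the computational core of a national survey of the
laccate *Ganoderma*: thirteen taxa (twelve *Ganoderma* species plus
*Tomophagus colossus*, with *G. curtisii* f.sp. *meredithiae* carried as a
distinct physiological taxon) identified from over 500 collections. Three
kinds of evidence are modelled — morphology (a dichotomous key and spore
morphometrics), collection metadata (tallies over species and host
substrate groups), and molecular data (a four-locus supermatrix, trees
with bootstrap support, and a locus-resolution scoring scheme).

All reference data ship as editable plain-text files under
`inst/extdata/`: the key, the per-taxon reference profiles, the color
synonym table, per-taxon spore statistics, the 507-collection species
counts, and the published taxa-by-loci support-score table.

## The identification key

The key is data, not code: twelve couplets in YAML, each lead a
conjunction of predicates over a `character_profile` and a forward
reference (another couplet or a taxon). Predicates are evaluated in
three-valued logic (true / false / undecidable). A couplet forwards down a
single lead only when that lead is affirmed and its sibling refuted; in
every other situation — a consulted character unobserved, or a spore mean
falling outside both printed ranges — the traversal follows *both* leads
and the answer is the union of candidates. Consequences:

* an uninformative profile returns all 13 taxa, never an error;
* information loss is monotone: masking a character can only grow the
  candidate set (a property the tests check for every taxon and
  character);
* every reference profile identifies exactly its own taxon
  (self-identification, checked for all 13).

Spore-size predicates use the printed per-taxon (min, max) ranges with
closed endpoints. Design choices made where the source material was open:

* "Missing" is an explicit state distinct from "absent": a specimen
  without melanoid deposits refutes a melanoid lead, a specimen whose
  context was never examined does not.
* The couplet separating *G. lucidum* encodes its restricted Utah /
  California range; a profile that says only `western_US` is treated as
  undecidable for that predicate (both leads followed), since introduced
  populations may spread.
* Subtropical south Florida is treated as matching "tropical locations"
  for *G. cf. weberianum* and *G. tuberculosum*; the vocabulary carries a
  single `subtropical` state.
* The printed key gives the *G. zonatum* spore-width range as 5.0–6.0 µm
  while the morphology table for the same taxon prints 5.9 (5.0–6.6); the
  shipped key uses the table's range so the taxon's own mean lies inside
  it.

`distinguishing_characters()` diffs two taxa's key paths and reports the
characters consulted at the first divergent couplet (e.g. growth rate on
malt extract agar for *G. curtisii* vs its forma specialis).

## Spore morphometrics

Per spore, with length measured from the base to the truncated apex and
width at the widest point (µm): `SSI = 100 · width / length` and
`Q = length / width`, so `SSI × Q = 100` exactly and both are invariant to
rescaling. Summaries average *per-spore* ratios, never ratios of means:
published per-taxon values are per-spore averages, and the ratio of the
printed mean dimensions can differ in the last decimal (e.g. one taxon
prints Q = 2.2 while its printed means give 11.2/5.2 ≈ 2.15). The package
therefore only asserts equality with printed values where the two
coincide at the printed rounding. Display rounding is one decimal, in the
`mean (min–max)` style. Tukey HSD letter groups are accepted as external
annotations for report rendering and are not recomputed (the per-spore raw
data behind them is not published).

Percentages in collection tallies use round-half-away-from-zero (base R's
banker's rounding would print 28.5% as 28) at integer precision by
default, with a one-decimal mode for rare classes (a 1-of-298 class prints
as 0% integer, 0.3% at one decimal). Over any complete partition the
rounded percentages sum to 100 within half a point per class.

## Desk-scale phylogenetics

The survey's inference used MAFFT alignment, RAxML (GTR, rapid
bootstrap, 1000 replicates) and MrBayes. Those engines are deliberately
out of scope here; the package provides a self-contained distance stage —
pairwise distances, neighbor joining, nonparametric bootstrap — sized for
a desk machine, and accepts externally produced support-annotated Newick
trees so the original ML/Bayesian pipeline can still be scored.

* **Distances.** p, JC69 (`-3/4 log(1 - 4p/3)`) and K2P, with *pairwise
  deletion*: only columns where both residues are plain `A/C/G/T` are
  compared, so the `?` padding of partial-taxon supermatrix rows does not
  destroy distances. Saturation (p ≥ 3/4, or non-positive K2P log
  arguments) and fully incomparable pairs are errors, not NaNs. The
  matrix route is vectorized with base-indicator cross-products and
  agrees with per-pair calls to 1e-12.
* **Neighbor joining** (Saitou–Nei Q-criterion) is written in-package
  because the contract pins behaviours stock implementations leave
  unspecified: ties in the minimal Q are broken by the lexicographically
  smallest pair of cluster labels (a cluster is labelled by its smallest
  tip), and negative branch-length estimates are clamped to zero with the
  deficit moved to the sister edge so the joined pair's distance is
  preserved. On additive matrices the generating tree is recovered
  exactly (topology and branch lengths); the tests verify this on 100
  random trees of up to 12 tips and cross-check topologies against
  `ape::nj` on noisy matrices.
* **Bootstrap.** Columns are resampled with replacement, distances and NJ
  recomputed per replicate, and each internal edge of the full-data tree
  is annotated with the percentage of replicates containing the same
  bipartition. Taxa are put in canonical order first, so supports are
  invariant to input order; a single integer seed makes runs exactly
  reproducible. Supports live in internal node labels (the usual Newick
  dialect); a comment dialect (`)[97]`) is supported for interchange.
  Unlabelled nodes mean "support absent", never 0.
* **Rooting and congruence.** Rooting requires the designated outgroup
  (two *Tomophagus* tips in the survey design) to be monophyletic in the
  unrooted sense. Congruence screening prunes trees to shared taxa and
  reports pairs of bipartitions that both meet a support floor (default
  75%) and are incompatible (all four side intersections non-empty); an
  empty report is the precondition for concatenation.

Partition coordinates are 1-based inclusive in files (`DNA, ITS = 1-521`)
and converted internally; concatenation pads taxa missing a locus with
`?`, and slicing a supermatrix by partition reproduces each input
alignment for its original taxa.

## The barcode-locus scoring scheme

For a support-annotated tree and a tip→species map, each species becomes a
record: `not_tested` when it has no tip in the tree, `resolved_unscored`
when it is a single-sample lineage (printed `R*`; no support value can
exist), `supported(s)` when its tips form one side of a bipartition with
support `s` at or above the floor, `monophyletic_below_threshold(s)` below
it, and `not_resolved` otherwise (including monophyletic clades on edges
without a support annotation). The locus score pair is the count
`#supported + #resolved_unscored` and the sum of supports over supported
clades only — a below-floor clade contributes to neither.

Interpretation choices, each pinned by arithmetic against the published
table:

* The floor comparison is `>= 75` although the published phrasing is
  "above 75": no printed support equals 75, so both readings reproduce
  the published totals, and the closed interval is simpler to reason
  about. Raising the floor is monotone (never increases either score),
  which the tests check across floors 0–100.
* `NR*` cells in the rpb2 column are read as resolved-but-unscored, the
  same as `R*`: the published rpb2 clade count of 8 requires 6 supported
  clades plus both `NR*` entries.
* The published prose total for *tef1α* (1070) disagrees with its table
  row and with the sum of the printed cells (both 970); the package
  follows the cells, and 970 is what the scoring reproduces.
* Single-sample lineages count toward the clade number (the published
  counts 12/11/8 are only reachable that way) but contribute nothing to
  the total score.
* `not_tested` is inferred from explicit absence in the map/tree, and an
  unmapped tip label is an error naming the tip, so typos fail loudly.

Monophyly is bipartition monophyly on the unrooted tree — a species whose
tips straddle the root-adjacent edge of a rooted drawing still scores —
and the decision procedure is verified against brute-force enumeration of
edge-induced bipartitions (an independent graph-components oracle) on all
tip subsets of trees up to 8 tips. When outgroup tips are declared, they
are removed from the bipartition universe for ingroup species; the
outgroup species itself, when mapped, is assessed on the full tree.

Loci are ranked by clade count, then total score, then name;
the name comparison is case-insensitive in C collation so ranking is
locale-independent.

## The synthetic generator

The generator produces every input the pipeline consumes, with planted
truth: a species tree (sequential random joins, uniform over join orders),
each species expanded into a shallow radiation, alignments evolved under
Jukes–Cantor, spore tables, and character profiles.

Defaults mirror the survey's dimensions: 13 species, 1–8 representatives
each, four loci of 521/764/615/570 columns (2470 concatenated), a two-tip
outgroup species, between-species depth 0.15 expected substitutions/site
(species-tree edges are 0.075 jittered by Unif(0.5, 1.5)) and
within-species depth 0.005. These depths put conspecific sequences within
a few substitutions of each other while separating species by dozens —
the regime in which the survey's loci operate and in which planted clades
should be recovered with high support. Spore draws are truncated normals
on the published per-taxon (min, max) ranges with the published mean and
`sd = (max − min)/4`, keeping ~95% of the untruncated mass in range.
JC is used for both simulation and distance estimation so the estimator is
correctly specified; simulating under JC and estimating under K2P is an
available experiment, not the default. All randomness flows from one
integer seed through named substreams (tree, per-locus sequences,
per-taxon spores, profiles), so components regenerate independently.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: indels and alignment error (columns are
homologous by construction), rate heterogeneity across sites and loci,
gene-tree/species-tree discordance (every locus evolves on the one true
tree), base-composition bias, and uneven locus sampling across taxa
(real rpb2 coverage was a quarter of ITS coverage). The end-to-end
recovery test — every planted multi-tip species `supported` at floor 75
and the concatenated matrix ranked first — validates the machinery, not
the hardness of real *Ganoderma* barcoding.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` wires simulate → concatenate → per-locus and concatenated
bootstrap NJ trees → clade assessment → locus ranking → a taxa-by-loci
report, writing a JSON manifest with the configuration, seed, package
version and an md5 checksum of every output; the same configuration and
seed reproduce identical trees and scores. A stage failure aborts with the
stage name. A thin CLI (`inst/scripts/ganokey-cli.R`) exposes `run`,
`simulate`, `score`, `identify` and `spores` subcommands; the R functions
are the primary interface.

The test suite exercises the full default-sized study (13 species, four
loci, 2470 columns, 100 bootstrap replicates per tree) once, and uses
smaller instances (3–8 species, 100–400 columns, 20–50 replicates)
elsewhere; brute-force oracles run on trees of at most 8 tips, where
enumeration is exact and fast. These sizes were chosen so the whole suite
completes in well under a minute on one core while still covering the
survey-scale configuration.

## Known limitations

* The distance/NJ stage is a stand-in for likelihood and Bayesian
  inference; on real, rate-heterogeneous data its supports will differ
  from RAxML's, which is why externally produced trees can be supplied to
  the scoring stage directly.
* The key encodes the published character states; specimens with
  character combinations outside the 13 reference profiles (hybrids,
  range expansions, misobserved colors) widen candidate sets rather than
  fail, which is intended but means a confident single answer is not
  guaranteed.
* The color synonym table covers the survey's vocabulary, not the full
  Ridgway standard; unmapped terms are deliberate errors so users extend
  the table consciously.
* Spore simulation treats length and width as independent truncated
  normals; real spores correlate the two axes, so simulated Q
  distributions are slightly wider than real ones.
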