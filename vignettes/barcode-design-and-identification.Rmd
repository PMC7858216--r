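---
title: "Designing chloroplast barcodes and identifying seed accessions"
author: "superbarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing chloroplast barcodes and identifying seed accessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superbarcode)
```

## The problem

Seed banks hold germplasm whose species labels are not always right:
taxonomy shifts, morphological identification of seeds is hard, and old
material gets contaminated. In groups of very closely related species —
the rice genus *Oryza* is the motivating case, with ~21 species in eight
deep "genome type" lineages, several of which radiated within the last
few million years — conventional plant barcodes (*matK*, *rbcL*,
*psbA-trnH*, ITS) separate the deep lineages but fail within them.

Two remedies work. A **super barcode** uses the entire chloroplast
genome as one marker: slow to obtain, but it accumulates enough fixed
differences to separate even sister species. A **group-specific
barcode** extracts the few most variable regions of that genome, so a
handful of PCR-sized fragments carries most of the discriminating
signal. This package implements the computational side of both: finding
the hypervariable regions, quantifying how well any marker separates the
species, and assigning query samples (seed accessions) to species with
an explicit mislabel verdict.

## Diversity scanning and region selection

Per-site nucleotide diversity over a set of aligned sequences is the
mean pairwise mismatch fraction

$$\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L_{\mathrm{used}}},$$

where $d_{ij}$ counts mismatches over the scored columns and
$L_{\mathrm{used}}$ counts the columns actually compared. The default
gap policy is **complete deletion**: a column containing a gap or
ambiguity code in any included sequence is dropped for everyone,
matching the convention of the classical sliding-window tools this scan
mirrors. Pairwise deletion is available when gappy alignments would
otherwise lose too many columns. A span with no usable columns reports
$\pi = 0$ with a degeneracy flag rather than NaN.

`sliding_scan()` computes $\pi$ and site-class counts in overlapping
windows; `select_regions()` ranks windows by $\pi$ (ties: more variable
sites, then leftmost start), consumes them in rank order while merging
overlapping or adjacent picks into maximal regions, and stops once the
requested number of regions of sufficient length exists. The stop-then-
truncate rule is deterministic without any seed, so two runs over the
same scan always select identical regions. Windows with $\pi = 0$ are
never selected: an invariant region cannot contribute a barcode.

Defaults — window 800, step 100, minimum region length 600, 36
candidates — are sized so that merged regions come out at the 1–1.6 kb
scale of PCR-amplifiable barcode fragments. The original study reported
its chosen regions in that size range but did not publish its window
parameters, so these are explicit, configurable choices rather than
reconstructions.

Site classes follow the parsimony conventions: a column is
*parsimony-informative* when at least two states are each carried by at
least two sequences; gaps and ambiguity codes are never states.

## Tree building and support

Discrimination and identification both rest on bootstrap-supported
clades, with two engines behind one interface:

* **Neighbor joining** on p-distances (or Jukes–Cantor corrected
  distances), via `ape::nj()`. Zero-length internal edges are collapsed
  before anything downstream reads the topology: NJ resolves ties
  arbitrarily (dependent on input order), and an edge with no length
  carries no signal. This mirrors the collapse-zero-branches default of
  classical parsimony software and is what makes supports invariant to
  row permutation.
* **Maximum parsimony**: replicated random stepwise addition followed by
  SPR branch swapping to a local optimum (via phangorn's search
  machinery), scored by a vectorised bitmask Fitch implementation in
  which gaps and ambiguity codes are (partial) wildcards with no cost of
  their own. The strict consensus of all distinct best trees is the
  point estimate. First-improvement SPR is used instead of full TBR:
  at barcode scale the SPR neighbourhoods already recover the exhaustive
  optimum on every small instance we test, and the historical TBR
  retention rules of legacy software are not unambiguously specifiable.
  The default of 10 addition replicates trades the study-scale 100 for
  desk-scale runtime and is configurable.

Bootstrap supports are computed by column resampling: each replicate
tree's bipartitions are tallied, and each internal edge of the point
tree is labelled with the percentage of replicates containing its
bipartition (integer, half-up rounding). Bipartitions are compared as
canonical leaf sets, so rooting never affects a support value. For
gap-free alignments the NJ bootstrap uses an algebraic shortcut — the
weighted mismatch counts of a column-resampled alignment are four
weighted crossproducts over the variable columns — which makes
200-replicate bootstraps of ~100-taxon, 20 kb alignments take seconds.

Rooting uses a designated outgroup (the study system roots on *Leersia*
species); a multi-taxon outgroup must be monophyletic on the unrooted
tree, otherwise the caller is told rather than silently mis-rooted.

## Discrimination power of a marker

A species is **resolved** by a marker when its samples form a clade
whose stem support exceeds the threshold (default 75, strict
comparison, following the "reliably resolvable above 75% bootstrap"
working rule for this kind of data). Monophyly is judged against
non-outgroup samples only, and the support reported is the species' own
stem edge — the smallest clade whose ingroup content is exactly the
species — not a complement edge that happens to induce the same
bipartition. Singleton species are resolved by convention (they cannot
fail monophyly) and report support `n/a`. Unresolved species are
grouped by the smallest supported clade containing them, which is how
reports express "this marker cannot separate species X, Y, Z".

`compare_markers()` applies this to any set of markers over the same
samples and ranks them, reproducing the study design of comparing
conventional barcodes, specific barcodes and the whole-genome super
barcode side by side.

## Identifying queries and flagging mislabels

`assign_queries()` places references and queries in one bootstrap tree
and walks from each query tip rootwards. The first ancestor clade that
(a) has stem support above the threshold and (b) contains at least one
non-outgroup reference decides: if its references belong to exactly one
species, the query is assigned to it; if they span several species the
query is `unresolved`. The walk never guesses — a query below the
threshold everywhere is `unresolved`, not nearest-neighbour assigned.
Clades containing only other queries are skipped rather than treated as
evidence. A synonym map can declare conspecific label sets so that a
query labelled with a synonym of its assigned species is `confirmed`.

The mislabel verdict is purely the comparison of assigned and given
labels; `mislabel_report()` summarises counts and the integer
percentage (9 flagged among 53 queries reports 17%).

The default identification engine is NJ with bootstrap; MP is available
and reaches the same verdicts on clean fixtures, but NJ's speed matters
when bootstrapping a hundred taxa against a 20 kb alignment.

## What the simulator emulates — and what it does not

`oryza_like_params()` encodes the study conditions as defaults:

* 8 clades ("genome types") holding 21 species (1–4 per clade), 1–3
  reference samples per species, two outgroup taxa;
* a 20 kb plastome-like alignment whose ingroup-wide diversity lands
  near 0.006, with six 800 bp hypervariable blocks whose rate
  multipliers (1.9–2.4) lift local diversity to the 0.01–0.02 range of
  real chloroplast barcode regions;
* two separate 1 kb nuclear-like loci at 12× and 20× the background
  rate, reaching diversities near 0.065 and 0.11, the regime of the
  fast nuclear genes used alongside plastomes;
* 53 query accessions with 17% of them deliberately mislabeled
  (`floor(0.17 * 53) = 9`), reassigned uniformly to a wrong species.

Divergence depths are fixed (inter-clade 0.006, inter-species 0.002,
intra-species 0.0002 expected substitutions per site) rather than drawn
from a coalescent: the signal being tested is clade separation, and a
fixed-depth hierarchy makes every expectation exact and every dataset
reproducible from one integer seed. Sequences evolve under Jukes–Cantor
with no indels by default; gap handling is exercised separately with
hand-built gapped fixtures, because indel realism is not what the
pipeline's statistics depend on.

Consequences for interpretation: passing tests on this simulator show
that the statistics and the assignment logic are correct and that the
pipeline recovers planted structure under realistic diversity levels.
They do not show robustness to alignment error, indel-rich regions,
chloroplast heteroplasmy, or introgression — none of which the
generator produces.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (R convention); BED-style
  half-open output can be derived trivially.
* Characters are uppercased on read; `U`→`T`, `?`→`N`; anything outside
  the IUPAC alphabet is a hard error with the offending record and
  column named.
* Ranking ties (windows, regions, markers) are broken deterministically
  (diversity, then variable-site count, then leftmost start), so no
  output depends on a seed except where bootstrap or simulation
  randomness is inherent — and those take explicit seed arguments.
* JC distances are capped at p = 0.7499 with a warning instead of
  returning infinities; pairs with no comparable columns are an error
  naming the pair.
* Supports are integers 0–100 with half-up rounding; `mislabel_report()`
  rounds its percentage the same way.

## Problem sizes used in validation

The shipped tests validate the core statistics against brute-force
oracles on hundreds of random instances (up to 12 taxa, 200 columns),
the MP search against exhaustive enumeration up to 8 taxa, NJ against
additive matrices up to 12 taxa, and the full pipeline on five
simulated datasets at the full preset scale (94 tips, 20 kb, 200
bootstrap replicates), requiring at least 95% recovery of planted
mislabels with zero false positives. The acceptance script
(`scripts/acceptance.R`) re-runs the preset pipeline for one seed and
reports the headline quantities.

## Known limitations

* Heuristic MP is a local search; on adversarial random data a handful
  of addition replicates can stall one step short of the optimum, which
  is why replicate counts are configurable (the tests use 20 where
  exhaustive equality is asserted).
* Strict-consensus polytomies make species inside an unresolved
  radiation count as unresolved even if some replicate trees separate
  them — deliberate, but worth knowing when reading resolution counts.
* The identification rule degrades to `unresolved` rather than guessing;
  on poorly resolved markers sensitivity to mislabels drops before
  false positives appear. This matches the conservative philosophy of
  tree-based identification: a flag should mean something.
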