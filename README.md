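# superbarcode

Design organellar DNA barcodes and identify specimens from them.

Seed banks and herbaria hold material whose species labels are not always
right, and in recently radiated groups (the rice genus *Oryza* is the
motivating system) the conventional plant barcodes cannot tell sister
species apart. This package implements the computational pipeline behind
group-specific and whole-plastome ("super") barcodes, for people who have
aligned chloroplast genomes and want to (1) find the hypervariable regions
worth sequencing, (2) measure how well any marker separates their species,
and (3) assign query samples — e.g. seed-bank accessions — to species with
an explicit mislabel verdict.

## What it computes

**Diversity scan.** Per-site nucleotide diversity over a column span,

    pi = 2 / (n (n-1)) * sum_{i<j} d_ij / L_used,

with complete-deletion gap handling by default, swept across the alignment
in sliding windows (`sliding_scan()`); candidate barcode regions are the
top-ranked windows merged into maximal non-overlapping regions
(`select_regions()`). Site classes (invariant / variable /
parsimony-informative / excluded) follow the standard parsimony
definitions (`classify_sites()`).

**Trees and support.** Neighbor joining on p- or JC-corrected distances
and heuristic maximum parsimony (random stepwise addition + SPR, Fitch
scoring with gaps as wildcards), with nonparametric bootstrap: supports
are the percentage of column-resampled replicate trees containing each
internal edge's bipartition. Trees are rooted on a designated outgroup.

**Discrimination.** A species is *resolved* by a marker when its samples
form a clade with stem bootstrap support above a threshold (default
`> 75`). `resolution_summary()` and `compare_markers()` score and rank
markers; unresolved species are reported grouped by the clade that
entangles them.

**Identification.** `assign_queries()` places queries in a joint
reference+query bootstrap tree; the smallest supported clade containing
the query and at least one reference decides the assignment, verdicts are
`confirmed` / `mislabeled` / `unresolved`, and `mislabel_report()`
summarises the counts and percentage.

**Simulation.** `simulate_dataset(oryza_like_params())` generates a
rice-like species complex — 8 clades, 21 species, hypervariable blocks,
fast nuclear-like loci, 53 queries with 17% planted mislabels — so the
whole pipeline is testable offline and every claim above can be checked
against planted truth.

## Worked example

```r
library(superbarcode)

ds  <- simulate_dataset(oryza_like_params(), seed = 11)
ing <- ds$samples$sample_id[!ds$samples$outgroup]

nucleotide_diversity(ds$alignment, include_ids = ing)
#> 0.00734 (whole-alignment diversity, the "super barcode" regime)

wins    <- sliding_scan(ds$alignment, window_length = 800, step = 100,
                        include_ids = ing)
regions <- select_regions(wins, n_candidates = 6, min_region_length = 600)
regions
#>       name start   end mean_pi rank
#> 1 region_1  4701  6000  0.0127    1
#> 2 region_2 13801 14900  0.0126    2
#> 3 region_3  2001  3000  0.0125    3
#> 4 region_4 16701 17800  0.0125    4
#> 5 region_5  8001  8800  0.0122    5
#> 6 region_6 10901 11700  0.0116    6

ident <- assign_queries(ds$alignment, ds$samples, method = "nj",
                        n_boot = 200, seed = 99)
mislabel_report(ident)
#> Queries: 53  mislabeled: 9 (17%)  confirmed: 44  unresolved: 0
#>   q003: labeled 'C3', assigned 'A2' (support 100)
#>   q016: labeled 'A3', assigned 'C1' (support 100)
#>   ...
```

The six selected regions sit on the simulator's six planted hypervariable
blocks; their diversities (~0.012) are roughly double the background, the
scale at which real chloroplast barcode regions sit above the rest of the
plastome. All nine planted mislabels are flagged with the correct
reassignment and nothing else is flagged; the 17% figure is the
integer-rounded share of flagged queries.

Real data enter through `read_alignment()` (aligned FASTA),
`read_sample_table()` (TSV: `sample_id`, `species`, `role`, `outgroup`)
and `read_newick()`; `extract_region()` and `concatenate_alignments()`
slice markers out of genome alignments and build concatenated barcodes.

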