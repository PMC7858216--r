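test_that("species trees respect the configured hierarchy", {
  p <- oryza_like_params(n_queries = 10L)
  st <- simulate_species_tree(p, seed = 3)
  expect_equal(nrow(st$species_map), 21L)
  expect_equal(length(unique(st$species_map$clade)), 8L)
  # leaf count = references + queries + outgroups
  expect_equal(length(st$tree$tip.label), nrow(st$truth))
  expect_equal(sum(st$truth$role == "query"), 10L)
  expect_equal(sum(st$truth$outgroup), 2L)

  # expected pairwise path lengths match the configured divergences
  d <- cophenetic(st$tree)
  pick <- function(sp) st$truth$sample_id[st$truth$true_species == sp][1]
  a1 <- pick("A1"); a2 <- pick("A2"); b1 <- pick("B1")
  expect_equal(d[a1, a2], p$inter_species_divergence, tolerance = 1e-9)
  expect_equal(d[a1, b1], p$inter_clade_divergence, tolerance = 1e-9)
  within <- st$truth$sample_id[st$truth$true_species == "A1"]
  if (length(within) >= 2) {
    expect_equal(d[within[1], within[2]], p$intra_species_divergence,
                 tolerance = 1e-9)
  }

  # determinism under a fixed seed
  st2 <- simulate_species_tree(p, seed = 3)
  expect_equal(ape::write.tree(st2$tree), ape::write.tree(st$tree))
  expect_equal(st2$truth, st$truth)

  expect_error(oryza_like_params(intra_species_divergence = 0.5), "intra <")
  expect_error(oryza_like_params(mislabel_fraction = 1.2), "mislabel_fraction")
})

test_that("zero branch lengths give identical sequences", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln <- simulate_alignment(tr, 200, seed = 2)
  expect_equal(aln_length(aln), 200L)
  expect_true(all(unclass(aln)[1, ] == unclass(aln)[2, ]))
  expect_true(all(unclass(aln)[1, ] == unclass(aln)[4, ]))
  expect_equal(as.numeric(nucleotide_diversity(aln)), 0)
})

test_that("two-leaf divergence matches the Jukes-Cantor closed form", {
  ell <- 0.01
  L <- 30000
  p_exp <- 0.75 * (1 - exp(-4 * ell / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", ell / 2, ell / 2))
  for (s in 1:8) {
    aln <- simulate_alignment(tr, L, seed = 100 + s)
    p_obs <- p_distance_matrix(aln)["a", "b"]
    expect_lt(abs(p_obs - p_exp), 3 * se)
  }
})

test_that("hypervariable blocks lift local diversity by about their multiplier", {
  p <- oryza_like_params(seq_length = 6000L, n_queries = 0L,
                         hypervariable_blocks = data.frame(
                           start = 2001L, end = 3000L, rate = 10),
                         nuclear_loci = NULL)
  st <- simulate_species_tree(p, seed = 17)
  aln <- simulate_alignment(st$tree, p$seq_length, p$hypervariable_blocks,
                            seed = 18)
  ing <- st$truth$sample_id[!st$truth$outgroup]
  bg <- as.numeric(nucleotide_diversity(aln, 1, 2000, include_ids = ing))
  blk <- as.numeric(nucleotide_diversity(aln, 2001, 3000, include_ids = ing))
  expect_gt(blk / bg, 5)
  expect_lt(blk / bg, 20)
})

test_that("mislabel planting hits the configured count, queries only", {
  p <- oryza_like_params()
  st <- simulate_species_tree(p, seed = 23)
  pm <- plant_mislabels(st$truth, 0.17, seed = 29)
  expect_equal(sum(pm$truth$is_planted_mislabel), 9L)  # floor(0.17 * 53)
  expect_true(all(pm$truth$role[pm$truth$is_planted_mislabel] == "query"))
  expect_equal(pm$truth$is_planted_mislabel,
               pm$truth$given_species != pm$truth$true_species)
  # the sample table carries the (possibly wrong) given labels
  expect_equal(pm$samples$species, pm$truth$given_species)

  none <- plant_mislabels(st$truth, 0, seed = 29)
  expect_equal(sum(none$truth$is_planted_mislabel), 0L)
  expect_equal(none$truth$given_species, none$truth$true_species)

  again <- plant_mislabels(st$truth, 0.17, seed = 29)
  expect_equal(again$truth, pm$truth)

  solo <- data.frame(sample_id = c("r1", "q1", "q2"), true_species = "X",
                     given_species = "X",
                     role = c("reference", "query", "query"),
                     outgroup = FALSE, stringsAsFactors = FALSE)
  expect_error(plant_mislabels(solo, 0.5, seed = 1), "fewer than 2")
})

test_that("the rice-like preset keeps whole-alignment diversity in its band", {
  p <- oryza_like_params(n_queries = 0L, nuclear_loci = NULL)
  for (s in 1:20) {
    st <- simulate_species_tree(p, seed = 1000 + s)
    aln <- simulate_alignment(st$tree, p$seq_length, p$hypervariable_blocks,
                              seed = 2000 + s)
    ing <- st$truth$sample_id[!st$truth$outgroup]
    pi <- as.numeric(nucleotide_diversity(aln, include_ids = ing))
    expect_gt(pi, 0.004)
    expect_lt(pi, 0.008)
  }
})

test_that("simulated datasets round-trip through FASTA and TSV without loss", {
  ds <- simulate_dataset(oryza_like_params(
    n_clades = 2, species_per_clade = 2L, n_queries = 5L,
    seq_length = 500L, hypervariable_blocks = NULL, nuclear_loci = NULL),
    seed = 31)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignment(ds$alignment, fa)
  write_sample_table(ds$samples, tsv)
  expect_identical(unclass(read_alignment(fa)), unclass(ds$alignment))
  expect_equal(read_sample_table(tsv), ds$samples)

  # dataset generation is reproducible from one integer
  ds2 <- simulate_dataset(oryza_like_params(
    n_clades = 2, species_per_clade = 2L, n_queries = 5L,
    seq_length = 500L, hypervariable_blocks = NULL, nuclear_loci = NULL),
    seed = 31)
  expect_identical(unclass(ds2$alignment), unclass(ds$alignment))
  expect_equal(ds2$samples, ds$samples)
})
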