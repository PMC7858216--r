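test_that("p-distances and JC correction match closed forms", {
  aln <- dna_alignment(c(a = "AAAA", b = "AATT", c = "AAAA"))
  D <- p_distance_matrix(aln)
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(D))

  # p = 0.1 over 10 sites -> jc = -0.75 log(1 - 0.4/3)
  aln2 <- dna_alignment(c(a = "AAAAAAAAAA", b = "TAAAAAAAAA"))
  J <- p_distance_matrix(aln2, model = "jc")
  expect_equal(J["a", "b"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(round(J["a", "b"], 6), 0.107326)

  # gaps make sites pairwise-incomparable
  aln3 <- dna_alignment(c(a = "AA--", b = "--TT"))
  expect_error(p_distance_matrix(aln3), "no comparable")

  sat <- dna_alignment(c(a = "AAAA", b = "TTTT", c = "AAAA"))
  expect_warning(p_distance_matrix(sat, model = "jc"), "saturated")
})

test_that("NJ recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,c:3,d:1);")
  d <- cophenetic(tr)
  nj <- nj_tree(d)
  expect_equal(phangorn::RF.dist(nj, tr), 0)
  expect_equal(cophenetic(nj)[rownames(d), colnames(d)], d, tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3")
  bad <- matrix(c(0, 1, 3, 2, 0, 1, 3, 2, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ recovers the generating topology on random additive matrices", {
  set.seed(21)
  for (i in 1:30) {
    ra <- random_additive(sample(4:10, 1))
    expect_equal(phangorn::RF.dist(nj_tree(ra$d), ra$tree), 0)
  }
})

test_that("Fitch scores match enumeration and phangorn on fixed cases", {
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  const <- dna_alignment(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA", t4 = "AAAA"))
  expect_equal(fitch_score(tr, const), 0L)
  one <- dna_alignment(c(t1 = "A", t2 = "A", t3 = "T", t4 = "T"))
  expect_equal(fitch_score(tr, one), 1L)
  two <- dna_alignment(c(t1 = "A", t2 = "T", t3 = "A", t4 = "T"))
  expect_equal(fitch_score(tr, two), 2L)
  # missing data costs nothing
  wild <- dna_alignment(c(t1 = "A", t2 = "-", t3 = "N", t4 = "A"))
  expect_equal(fitch_score(tr, wild), 0L)
  bad <- dna_alignment(c(x = "A", y = "A", z = "A", w = "A"))
  expect_error(fitch_score(tr, bad), "do not match")
})

test_that("Fitch agrees with the recursive oracle and phangorn on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    aln <- random_aln(n, sample(5:40, 1), gap_frac = sample(c(0, 0.1), 1))
    tr <- ape::rtree(n, tip.label = rownames(aln))
    sc <- fitch_score(tr, aln)
    expect_equal(sc, brute_fitch(tr, aln))
    dat <- phangorn::phyDat(unclass(aln), type = "DNA")
    expect_equal(sc, as.integer(phangorn::parsimony(tr, dat, method = "fitch")))
  }
})

test_that("MP search finds the known optimum and is deterministic", {
  aln <- dna_alignment(c(t1 = "AAAAA", t2 = "AAAAA", t3 = "TTTTT", t4 = "TTTTT"))
  res <- mp_search(aln, n_addition_replicates = 3, seed = 1)
  expect_equal(attr(res, "score"), 5L)
  expect_true(ape::is.monophyletic(res[[1]], c("t1", "t2")))

  set.seed(41)
  aln2 <- random_aln(7, 30)
  r1 <- mp_search(aln2, n_addition_replicates = 3, seed = 7)
  r2 <- mp_search(aln2, n_addition_replicates = 3, seed = 7)
  expect_equal(attr(r1, "score"), attr(r2, "score"))
  expect_equal(length(r1), length(r2))
  for (k in seq_along(r1)) expect_equal(phangorn::RF.dist(r1[[k]], r2[[k]]), 0)

  expect_error(mp_search(random_aln(3, 10)), ">= 4")
})

test_that("MP best score is never worse than the NJ tree's score", {
  set.seed(51)
  for (i in 1:10) {
    aln <- random_aln(sample(5:9, 1), 40)
    nj <- nj_tree(p_distance_matrix(aln))
    best <- attr(mp_search(aln, n_addition_replicates = 3, seed = i), "score")
    expect_lte(best, fitch_score(nj, aln))
  }
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  same <- strict_consensus(list(t1, t1))
  expect_equal(phangorn::RF.dist(same, t1), 0)

  # no shared internal bipartition -> star tree
  ta <- ape::read.tree(text = "((a,b),(c,d));")
  tb <- ape::read.tree(text = "((a,c),(b,d));")
  star <- strict_consensus(list(ta, tb))
  expect_equal(star$Nnode, 1L)

  set.seed(61)
  for (i in 1:15) {
    n <- sample(6:15, 1)
    trees <- lapply(1:3, function(k) ape::rtree(n, tip.label = paste0("t", 1:n)))
    cons <- strict_consensus(trees)
    shared <- Reduce(intersect, lapply(trees, superbarcode:::bipartition_keys))
    expect_setequal(superbarcode:::bipartition_keys(cons), shared)
  }

  t_bad <- ape::rtree(5)
  expect_error(strict_consensus(list(t1, t_bad)), "leaf sets")
})

test_that("bootstrap saturates on clean signal and rounds to integers", {
  aln <- dna_alignment(rbind(
    a1 = rep(c("A", "C"), each = 30), a2 = rep(c("A", "C"), each = 30),
    b1 = rep(c("T", "G"), each = 30), b2 = rep(c("T", "G"), each = 30),
    b3 = rep(c("T", "G"), each = 30)))
  tr <- bootstrap_tree(aln, method = "nj", n_reps = 100, seed = 2)
  sup <- suppressWarnings(as.integer(tr$node.label))
  expect_true(100 %in% sup)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))

  one <- bootstrap_tree(aln, method = "nj", n_reps = 1, seed = 3)
  s1 <- suppressWarnings(as.integer(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0L, 100L)))
})

test_that("bootstrap supports are row-order invariant and seed-stable within noise", {
  set.seed(71)
  ds <- simulate_dataset(oryza_like_params(
    n_clades = 3, species_per_clade = c(2L, 2L, 2L), n_queries = 0L,
    seq_length = 3000L, hypervariable_blocks = NULL, nuclear_loci = NULL),
    seed = 5)
  aln <- ds$alignment
  t1 <- bootstrap_tree(aln, n_reps = 200, seed = 11)
  perm <- unclass(aln)[sample(nrow(aln)), , drop = FALSE]
  class(perm) <- class(aln)
  t2 <- bootstrap_tree(perm, n_reps = 200, seed = 11)
  t3 <- bootstrap_tree(aln, n_reps = 200, seed = 12)
  key_sup <- function(tr) {
    n_tip <- length(tr$tip.label)
    ks <- vapply((n_tip + 1):(n_tip + tr$Nnode), function(nd)
      superbarcode:::node_bipartition_key(tr, nd, tr$tip.label), character(1))
    s <- superbarcode:::node_supports(tr)
    stats::setNames(s[!is.na(ks)], ks[!is.na(ks)])
  }
  s1 <- key_sup(t1); s2 <- key_sup(t2); s3 <- key_sup(t3)
  common12 <- intersect(names(s1), names(s2))
  expect_true(length(common12) > 0)
  expect_equal(s1[common12], s2[common12])
  common13 <- intersect(names(s1), names(s3))
  expect_true(all(abs(s1[common13] - s3[common13]) <= 10))
})

test_that("outgroup rooting places the root on the outgroup edge", {
  tr <- ape::read.tree(text = "((a,b),(c,o));")
  r <- root_with_outgroup(tr, "o")
  expect_true(ape::is.rooted(r))
  expect_true(ape::is.monophyletic(r, c("a", "b", "c")))

  tr2 <- ape::read.tree(text = "(((o1,o2),a),(b,c));")
  r2 <- root_with_outgroup(tr2, c("o1", "o2"))
  expect_true(ape::is.monophyletic(r2, c("o1", "o2")))
  expect_true(ape::is.monophyletic(r2, c("a", "b", "c")))

  tr3 <- ape::read.tree(text = "((o1,a),(o2,b),c);")
  expect_error(root_with_outgroup(tr3, c("o1", "o2")), "monophyletic")
  expect_error(root_with_outgroup(tr, "zzz"), "not in tree")
})
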