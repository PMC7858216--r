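# Bitmask encoding of IUPAC codes for Fitch: A=1, C=2, G=4, T=8;
# ambiguity codes are unions; gap/N/? are full wildcards (missing data).
IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
                V = 7L, H = 11L, D = 13L, B = 14L, N = 15L, "-" = 15L)

dna_codes <- function(aln) {
  # integer codes 1..4 for definite bases, 0 for gap/ambiguity
  m <- match(unclass(aln), DNA_BASES, nomatch = 0L)
  dim(m) <- dim(aln)
  rownames(m) <- rownames(aln)
  m
}

#' Pairwise distance matrix from an alignment
#'
#' `model = "p"` gives the proportion of mismatching sites over
#' pairwise-complete columns (both sequences carry a definite base;
#' gaps and ambiguity codes are treated as missing). `model = "jc"`
#' applies the Jukes-Cantor correction \eqn{-\frac{3}{4}\ln(1 - 4p/3)};
#' saturated pairs (p >= 0.75) are capped at the correction for
#' p = 0.7499 with a warning.
#'
#' @param aln a [dna_alignment] with >= 2 sequences.
#' @param model `"p"` (default) or `"jc"`.
#' @return symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance_matrix <- function(aln, model = c("p", "jc")) {
  model <- match.arg(model)
  X <- dna_codes(aln)
  n <- nrow(X)
  if (n < 2L) stop("distance matrix needs >= 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  def <- X > 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- def[i, ] & def[j, ]
      nc <- sum(comp)
      if (nc == 0L) stop("no comparable columns between '", rownames(X)[i],
                         "' and '", rownames(X)[j], "'")
      p <- sum(X[i, comp] != X[j, comp]) / nc
      D[i, j] <- D[j, i] <- p
    }
  }
  if (model == "jc") {
    sat <- D >= 0.75
    if (any(sat)) {
      warning("saturated pair(s) with p >= 0.75; JC distance capped")
      D[sat] <- 0.7499
    }
    D <- -0.75 * log(1 - 4 * D / 3)
    diag(D) <- 0
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining on a symmetric distance matrix (via
#' [ape::nj()]); deterministic for a given input.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @return unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor-joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  ape::nj(d)
}

#' Fitch parsimony length of a tree
#'
#' Vectorised bitmask Fitch over all columns: gaps and ambiguity codes act
#' as (partial) wildcards and never add cost on their own.
#'
#' @param tree an [ape::phylo] tree whose tip labels match the alignment
#'   ids (rooted or unrooted; polytomies allowed).
#' @param aln a [dna_alignment].
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  if (!setequal(tree$tip.label, rownames(aln))) {
    stop("tree leaves and alignment ids do not match")
  }
  L <- ncol(aln)
  bits <- IUPAC_BITS[unclass(aln)]
  dim(bits) <- dim(aln)
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  sets <- matrix(0L, n_tip + tree$Nnode, L)
  sets[seq_len(n_tip), ] <- bits[match(tree$tip.label, rownames(aln)), , drop = FALSE]
  cost <- 0L
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  for (e in seq_along(parent)) {
    p <- parent[e]
    s <- sets[p, ]
    cs <- sets[child[e], ]
    if (all(s == 0L)) {
      sets[p, ] <- cs
    } else {
      inter <- bitwAnd(s, cs)
      empty <- inter == 0L
      cost <- cost + sum(empty)
      inter[empty] <- bitwOr(s[empty], cs[empty])
      sets[p, ] <- inter
    }
  }
  as.integer(cost)
}

#' Heuristic maximum-parsimony search
#'
#' Replicated random stepwise addition followed by local branch swapping
#' (SPR by default, first-improvement), as in standard heuristic MP
#' searches. Returns the set of distinct best-score trees found.
#'
#' @param aln a [dna_alignment] with >= 4 sequences.
#' @param n_addition_replicates number of random-addition replicates
#'   (default 10).
#' @param swap branch-swapping scheme: `"spr"` (default), `"nni"`, or
#'   `"none"`.
#' @param max_trees_kept cap on the number of distinct best trees returned.
#' @param seed integer seed controlling the random addition orders; fixed
#'   seed gives identical output.
#' @return a `multiPhylo` list of unrooted best trees, with attribute
#'   `score` (the shared Fitch score).
#' @export
mp_search <- function(aln, n_addition_replicates = 10L,
                      swap = c("spr", "nni", "none"),
                      max_trees_kept = 100L, seed = NULL) {
  swap <- match.arg(swap)
  if (nrow(aln) < 4L) stop("MP search needs >= 4 taxa")
  if (n_addition_replicates < 1L) stop("n_addition_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dat <- phangorn::phyDat(unclass(aln), type = "DNA")
  best_score <- Inf
  best <- list()
  best_keys <- character()
  for (r in seq_len(n_addition_replicates)) {
    tr <- phangorn::random.addition(dat)
    if (swap != "none") {
      tr <- phangorn::optim.parsimony(
        tr, dat, method = "fitch", trace = 0,
        rearrangements = if (swap == "spr") "SPR" else "NNI")
    }
    sc <- fitch_score(tr, aln)
    if (sc < best_score) {
      best_score <- sc
      best <- list()
      best_keys <- character()
    }
    if (sc == best_score && length(best) < max_trees_kept) {
      key <- paste(sort(bipartition_keys(tr)), collapse = ";")
      if (!(key %in% best_keys)) {
        best <- c(best, list(tr))
        best_keys <- c(best_keys, key)
      }
    }
  }
  class(best) <- "multiPhylo"
  attr(best, "score") <- best_score
  best
}

#' Strict consensus of trees
#'
#' Retains exactly the bipartitions present in every input tree.
#'
#' @param trees a list / `multiPhylo` of trees over identical leaf sets.
#' @return an [ape::phylo] consensus tree.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  if (length(trees) == 0L) stop("no trees")
  ref <- trees[[1L]]$tip.label
  for (t in trees) {
    if (!setequal(t$tip.label, ref)) stop("trees have different leaf sets")
  }
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, check.labels = TRUE)
}

# Canonical keys for the non-trivial bipartitions of a tree: each internal
# edge is represented by the leaf set on the side NOT containing the
# alphabetically first leaf, sorted and collapsed. Rooting-invariant.
bipartition_keys <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  if (n < 4L) return(character())
  anchor <- min(labs)
  pp <- ape::prop.part(tree)
  keys <- character()
  for (cl in pp) {
    side <- labs[cl]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

# Clade key (same canonical form) for one internal node of a tree.
node_bipartition_key <- function(tree, node, labs = tree$tip.label) {
  tips <- clade_tips(tree, node)
  side <- labs[tips]
  anchor <- min(labs)
  if (anchor %in% side) side <- setdiff(labs, side)
  if (length(side) < 2L || length(side) > length(labs) - 2L) return(NA_character_)
  paste(sort(side), collapse = "\r")
}

# Tip indices below a node (node may be a tip).
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  tips <- integer()
  stack <- node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= n_tip) tips <- c(tips, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  tips
}

#' Bootstrap a tree with bipartition supports
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with the chosen engine, and annotates each internal edge of
#' the point-estimate tree with the percentage of replicate trees
#' containing that bipartition (integer, half-up rounding). When outgroup
#' ids are supplied the point tree is rooted on them before annotation.
#'
#' The point estimate is the NJ tree of the p-distance matrix
#' (`method = "nj"`) or the strict consensus of a heuristic MP search
#' (`method = "mp"`). Replicate MP searches use a single addition replicate
#' with NNI swapping to keep the bootstrap tractable.
#'
#' @param aln a [dna_alignment].
#' @param method `"nj"` (default) or `"mp"`.
#' @param n_reps number of bootstrap replicates (default 200).
#' @param seed integer seed for resampling (and MP addition orders).
#' @param outgroup optional character vector of outgroup ids for rooting.
#' @param mp_args list of arguments for the point-estimate [mp_search()].
#' @return an [ape::phylo] tree whose `node.label` holds integer supports
#'   (`""` on the root), with attributes `n_reps`, `method`, `seed`.
#' @export
bootstrap_tree <- function(aln, method = c("nj", "mp"), n_reps = 200L,
                           seed = NULL, outgroup = NULL,
                           mp_args = list()) {
  method <- match.arg(method)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  point <- if (method == "nj") {
    # collapse zero-length internal edges: NJ resolves them arbitrarily
    # and they carry no signal (cf. PAUP's collapse-zero-branches default)
    collapse_zero(nj_tree(p_distance_matrix(aln)))
  } else {
    strict_consensus(do.call(mp_search, c(list(aln = aln), mp_args)))
  }
  if (!is.null(outgroup) && length(outgroup)) {
    point <- root_with_outgroup(point, outgroup)
  }
  counts <- count_bipartitions(aln, method, n_reps)
  annotate_supports(point, counts, n_reps)
}

collapse_zero <- function(tr) {
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::di2multi(tr, tol = 1e-10)
}

# Tally bipartition keys over bootstrap replicates.
count_bipartitions <- function(aln, method, n_reps) {
  L <- ncol(aln)
  fast <- method == "nj" && all(unclass(aln) %in% DNA_BASES)
  env <- if (fast) nj_boot_env(aln) else NULL
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(n_reps)) {
    tr <- if (fast) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      collapse_zero(nj_tree(env$dist_from_weights(w)))
    } else {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- structure(unclass(aln)[, cols, drop = FALSE],
                       class = c("dna_alignment", "matrix", "array"))
      if (method == "nj") collapse_zero(nj_tree(p_distance_matrix(sub)))
      else strict_consensus(mp_search(sub, n_addition_replicates = 1L,
                                      swap = "nni"))
    }
    for (k in bipartition_keys(tr)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  counts
}

# Precomputation for fast NJ bootstrapping of gap-free alignments:
# mismatch counts under column reweighting reduce to four weighted
# crossproducts over the variable columns.
nj_boot_env <- function(aln) {
  X <- dna_codes(aln)
  n <- nrow(X)
  L <- ncol(X)
  state_n <- apply(X, 2L, function(col) length(unique(col)))
  V <- which(state_n > 1L)
  B <- lapply(1:4, function(s) (X[, V, drop = FALSE] == s) * 1)
  ids <- rownames(X)
  env <- new.env()
  env$dist_from_weights <- function(w) {
    wV <- w[V]
    tot <- sum(wV)
    matches <- matrix(0, n, n)
    for (s in 1:4) {
      Bs <- B[[s]]
      matches <- matches + Bs %*% (wV * t(Bs))
    }
    D <- (tot - matches) / L
    diag(D) <- 0
    dimnames(D) <- list(ids, ids)
    D
  }
  env
}

# Write integer supports onto the internal nodes of `point`.
annotate_supports <- function(point, counts, n_reps) {
  n_tip <- length(point$tip.label)
  labs <- point$tip.label
  node.label <- character(point$Nnode)
  for (i in seq_len(point$Nnode)) {
    node <- n_tip + i
    key <- node_bipartition_key(point, node, labs)
    if (is.na(key)) { node.label[i] <- ""; next }
    cnt <- counts[[key]]
    if (is.null(cnt)) cnt <- 0L
    node.label[i] <- as.character(floor(100 * cnt / n_reps + 0.5))
  }
  point$node.label <- node.label
  attr(point, "n_reps") <- n_reps
  point
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup.
#' With more than one outgroup id, the outgroup must form a clade on the
#' unrooted tree.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup_ids character vector of outgroup tip labels.
#' @return rooted [ape::phylo] tree (node labels, e.g. supports, preserved
#'   on the correct edges).
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  missing_ids <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing_ids)) stop("outgroup id(s) not in tree: ",
                                paste(missing_ids, collapse = ", "))
  if (length(outgroup_ids) > 1L &&
      !ape::is.monophyletic(tree, outgroup_ids)) {
    stop("outgroup is not monophyletic on the tree")
  }
  ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE,
            edgelabel = TRUE)
}

# Integer supports per internal node (NA where blank/root).
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_integer_, tree$Nnode))
  suppressWarnings(as.integer(tree$node.label))
}
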