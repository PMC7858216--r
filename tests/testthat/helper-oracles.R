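# Independent brute-force oracles, deliberately written in the most naive
# style possible (explicit loops, character sets) so they share no code
# with the package internals.

BASES <- c("A", "C", "G", "T")

random_aln <- function(n, L, gap_frac = 0) {
  mat <- matrix(sample(BASES, n * L, replace = TRUE), n, L)
  if (gap_frac > 0) {
    k <- rbinom(1, n * L, gap_frac)
    if (k > 0) mat[sample(n * L, k)] <- sample(c("-", "N"), k, replace = TRUE)
  }
  rownames(mat) <- paste0("t", seq_len(n))
  dna_alignment(mat)
}

# pi under complete deletion: all-pairs mismatch loop
brute_pi <- function(aln) {
  mat <- unclass(aln)
  n <- nrow(mat)
  keep <- apply(mat, 2, function(col) all(col %in% BASES))
  L <- sum(keep)
  if (L == 0) return(0)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mat[i, keep] != mat[j, keep])
  }
  (2 / (n * (n - 1))) * tot / L
}

brute_classes <- function(aln) {
  mat <- unclass(aln)
  sapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(!(col %in% BASES))) return("excluded")
    tab <- table(col)
    if (length(tab) < 2) return("invariant")
    if (sum(tab >= 2) >= 2) return("parsimony_informative")
    "variable"
  })
}

# IUPAC expansion for the set-based Fitch oracle
expand_base <- function(ch) {
  switch(ch,
         A = "A", C = "C", G = "G", T = "T",
         M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
         S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
         V = c("A", "C", "G"), H = c("A", "C", "T"),
         D = c("A", "G", "T"), B = c("C", "G", "T"),
         BASES)  # N, -, anything else: wildcard
}

# Recursive Fitch score, one column at a time, sets as character vectors.
brute_fitch <- function(tree, aln) {
  mat <- unclass(aln)
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  total <- 0
  for (j in seq_len(ncol(mat))) {
    cost <- 0
    rec <- function(node) {
      if (node <= n_tip) {
        return(expand_base(mat[tree$tip.label[node], j]))
      }
      s <- NULL
      for (ch in kids[[as.character(node)]]) {
        cs <- rec(ch)
        if (is.null(s)) s <- cs
        else {
          inter <- intersect(s, cs)
          if (length(inter) == 0) {
            cost <<- cost + 1
            s <- union(s, cs)
          } else s <- inter
        }
      }
      s
    }
    rec(n_tip + 1)
    total <- total + cost
  }
  total
}

# exhaustive MP optimum: enumerate all unrooted binary topologies
exhaustive_mp_score <- function(aln) {
  trees <- phangorn::allTrees(nrow(aln), rooted = FALSE,
                              tip.label = rownames(aln))
  min(vapply(trees, function(t) fitch_score(t, aln), integer(1)))
}

# random additive distance matrix from a random unrooted tree
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  list(tree = tr, d = cophenetic(tr))
}

# independent region-selection oracle: sort, greedily merge, truncate,
# implemented with a plain data.frame walk
oracle_select <- function(windows, n_candidates, min_len) {
  w <- windows[order(-windows$pi, -windows$n_variable, windows$start), ]
  regs <- data.frame(start = integer(), end = integer())
  members <- list()
  for (k in seq_len(nrow(w))) {
    if (w$pi[k] <= 0) break
    touch <- which(w$start[k] <= regs$end + 1 & w$end[k] >= regs$start - 1)
    if (length(touch) > 0) {
      new_start <- min(c(w$start[k], regs$start[touch]))
      new_end <- max(c(w$end[k], regs$end[touch]))
      new_members <- c(do.call(c, members[touch]), list(w[k, ]))
      regs <- regs[-touch, , drop = FALSE]
      members <- members[-touch]
      regs <- rbind(regs, data.frame(start = new_start, end = new_end))
      members <- c(members, list(new_members))
    } else {
      regs <- rbind(regs, data.frame(start = w$start[k], end = w$end[k]))
      members <- c(members, list(list(w[k, ])))
    }
    if (sum(regs$end - regs$start + 1 >= min_len) >= n_candidates) break
  }
  ok <- regs$end - regs$start + 1 >= min_len
  regs <- regs[ok, , drop = FALSE]
  members <- members[ok]
  if (nrow(regs) == 0) return(regs)
  regs$mean_pi <- sapply(members, function(m) mean(sapply(m, `[[`, "pi")))
  regs$nvar <- sapply(members, function(m) sum(sapply(m, `[[`, "n_variable")))
  regs <- regs[order(-regs$mean_pi, -regs$nvar, regs$start), ]
  head(regs, n_candidates)
}

# small well-separated two-species fixture used across identify tests:
# nd diagnostic columns per species, nc shared constant columns
two_species_aln <- function(n_per = 3, nd = 30, nc = 100) {
  a_row <- c(rep("A", nd), rep("C", nd), rep("G", nc))
  b_row <- c(rep("T", nd), rep("C", nd), rep("G", nc))
  o_row <- c(rep("C", nd), rep("T", nd), rep("G", nc))
  rows <- rbind(
    matrix(rep(a_row, n_per), n_per, byrow = TRUE),
    matrix(rep(b_row, n_per), n_per, byrow = TRUE),
    o_row)
  rownames(rows) <- c(paste0("a", 1:n_per), paste0("b", 1:n_per), "og")
  dna_alignment(rows)
}

two_species_samples <- function(n_per = 3) {
  data.frame(
    sample_id = c(paste0("a", 1:n_per), paste0("b", 1:n_per), "og"),
    species = c(rep("spA", n_per), rep("spB", n_per), "outgroup_sp"),
    role = "reference",
    outgroup = c(rep(FALSE, 2 * n_per), TRUE),
    stringsAsFactors = FALSE)
}
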