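#' Parameters for the rice-like synthetic species complex
#'
#' Defaults emulate the structure of the *Oryza* study system: 8 deep
#' clades ("genome types") holding 21 species (1-4 per clade), 1-3
#' reference samples per species, a ~20 kb plastome-like alignment with
#' background diversity near 0.006 and six hypervariable blocks reaching
#' pi of 0.01-0.02, two nuclear-like loci with pi of 0.06-0.12, two
#' outgroup taxa, 53 query accessions and a 17% planted-mislabel rate.
#' Divergences are expected substitutions per site between tips
#' (intra-species < inter-species < inter-clade).
#'
#' @param ... named overrides of any default listed above.
#' @return object of class `sim_params`.
#' @export
oryza_like_params <- function(...) {
  p <- list(
    n_clades = 8L,
    species_per_clade = c(4L, 2L, 4L, 1L, 1L, 3L, 3L, 3L),
    samples_per_species = c(1L, 3L),
    n_queries = 53L,
    mislabel_fraction = 0.17,
    seq_length = 20000L,
    inter_clade_divergence = 0.006,
    inter_species_divergence = 0.002,
    intra_species_divergence = 0.0002,
    hypervariable_blocks = data.frame(
      start = c(2001L, 5001L, 8001L, 11001L, 14001L, 17001L),
      end = c(2800L, 5800L, 8800L, 11800L, 14800L, 17800L),
      rate = c(2.2, 2.0, 2.4, 1.9, 2.3, 2.1)),
    nuclear_loci = data.frame(
      name = c("np78_like", "r22_like"),
      length = c(1000L, 1000L),
      rate = c(12, 20), stringsAsFactors = FALSE),
    n_outgroups = 2L,
    outgroup_divergence = 0.03
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  if (!(p$intra_species_divergence < p$inter_species_divergence &&
        p$inter_species_divergence < p$inter_clade_divergence)) {
    stop("divergences must satisfy intra < inter_species < inter_clade")
  }
  if (p$mislabel_fraction < 0 || p$mislabel_fraction >= 1) {
    stop("mislabel_fraction must be in [0, 1)")
  }
  if (!is.null(p$hypervariable_blocks) && nrow(p$hypervariable_blocks)) {
    if (any(p$hypervariable_blocks$rate < 1)) stop("block rate multipliers must be >= 1")
  }
  if (length(p$species_per_clade) == 1L) {
    p$species_per_clade <- rep(p$species_per_clade, p$n_clades)
  }
  if (length(p$species_per_clade) != p$n_clades) {
    stop("species_per_clade must have one entry per clade")
  }
  p
}


#' Simulate the sample-level species tree
#'
#' A fixed-depth hierarchy rather than a coalescent: clade lineages split
#' at half the inter-clade divergence from the tips, species within a
#' clade at half the inter-species divergence, and samples within a
#' species at half the intra-species divergence, so expected pairwise path
#' lengths equal the configured divergences. Outgroup tips attach at half
#' the outgroup divergence. Reference sample counts and query placements
#' are drawn from the seeded generator.
#'
#' @param params a `sim_params` object, see [oryza_like_params()].
#' @param seed integer seed (optional; the current RNG state is used when
#'   absent).
#' @return list with `tree` ([ape::phylo], branch lengths in expected
#'   substitutions/site), `species_map` (species to clade), and `truth`
#'   (per-sample table: `sample_id`, `true_species`, `given_species`,
#'   `role`, `outgroup`).
#' @export
simulate_species_tree <- function(params, seed = NULL) {
  params <- validate_sim_params(params)
  if (!is.null(seed)) set.seed(seed)
  d_cl <- params$inter_clade_divergence / 2
  d_sp <- params$inter_species_divergence / 2
  d_sa <- params$intra_species_divergence / 2
  d_out <- params$outgroup_divergence / 2
  clades <- LETTERS[seq_len(params$n_clades)]
  species <- unlist(lapply(seq_len(params$n_clades), function(i) {
    paste0(clades[i], seq_len(params$species_per_clade[i]))
  }))
  species_map <- data.frame(
    species = species,
    clade = rep(clades, params$species_per_clade),
    stringsAsFactors = FALSE)
  rng <- params$samples_per_species
  n_samples <- sample(rng[1L]:rng[2L], length(species), replace = TRUE)
  q_species <- if (params$n_queries > 0L) {
    sort(sample(species, params$n_queries, replace = TRUE))
  } else character()
  truth_rows <- list()
  sp_tip_text <- stats::setNames(vector("list", length(species)), species)
  qk <- 0L
  for (si in seq_along(species)) {
    sp <- species[si]
    refs <- paste0(sp, "_r", seq_len(n_samples[si]))
    nq <- sum(q_species == sp)
    qids <- if (nq > 0L) sprintf("q%03d", qk + seq_len(nq)) else character()
    qk <- qk + nq
    tips <- c(refs, qids)
    truth_rows[[si]] <- data.frame(
      sample_id = tips, true_species = sp, given_species = sp,
      role = c(rep("reference", length(refs)), rep("query", nq)),
      outgroup = FALSE, stringsAsFactors = FALSE)
    sp_tip_text[[sp]] <- tips
  }
  node_text <- function(children, depth_parent, depth_node) {
    paste0("(", paste(children, collapse = ","), "):",
           format(depth_parent - depth_node, scientific = FALSE))
  }
  clade_text <- vapply(seq_along(clades), function(ci) {
    sps <- species_map$species[species_map$clade == clades[ci]]
    sp_text <- vapply(sps, function(sp) {
      tips <- sp_tip_text[[sp]]
      top <- if (length(sps) == 1L) d_cl else d_sp
      if (length(tips) == 1L) {
        paste0(tips, ":", format(top, scientific = FALSE))
      } else {
        node_text(paste0(tips, ":", format(d_sa, scientific = FALSE)), top, d_sa)
      }
    }, character(1L))
    if (length(sps) == 1L) sp_text
    else node_text(sp_text, d_cl, d_sp)
  }, character(1L))
  ingroup <- node_text(clade_text, d_out, d_cl)
  og_tips <- if (params$n_outgroups > 0L) {
    paste0("OUT", seq_len(params$n_outgroups), ":",
           format(d_out, scientific = FALSE))
  } else character()
  newick <- paste0("(", paste(c(og_tips, ingroup), collapse = ","), ");")
  tree <- ape::read.tree(text = newick)
  truth <- do.call(rbind, truth_rows)
  if (params$n_outgroups > 0L) {
    truth <- rbind(truth, data.frame(
      sample_id = paste0("OUT", seq_len(params$n_outgroups)),
      true_species = "outgroup_sp", given_species = "outgroup_sp",
      role = "reference", outgroup = TRUE, stringsAsFactors = FALSE))
  }
  rownames(truth) <- NULL
  list(tree = tree, species_map = species_map, truth = truth)
}

#' Simulate an alignment along a tree
#'
#' Jukes-Cantor evolution via [phangorn::simSeq()]; columns inside
#' `blocks` evolve with branch lengths scaled by the block's rate
#' multiplier (localised rate heterogeneity, no indels).
#'
#' @param tree an [ape::phylo] tree with branch lengths in expected
#'   substitutions/site.
#' @param seq_length number of columns.
#' @param blocks optional data.frame with `start`, `end` (1-based
#'   inclusive, non-overlapping, within the sequence) and `rate`
#'   multipliers (>= 1).
#' @param seed integer seed (optional).
#' @return a [dna_alignment] with one row per tree tip.
#' @export
simulate_alignment <- function(tree, seq_length, blocks = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- data.frame(start = 1L, end = as.integer(seq_length), rate = 1)
  if (!is.null(blocks) && nrow(blocks)) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (any(blocks$start > blocks$end) || any(blocks$start < 1L) ||
        any(blocks$end > seq_length)) stop("block out of range")
    if (any(utils::head(blocks$end, -1L) >= utils::tail(blocks$start, -1L))) {
      stop("blocks overlap")
    }
    segs <- NULL
    pos <- 1L
    for (b in seq_len(nrow(blocks))) {
      if (blocks$start[b] > pos) {
        segs <- rbind(segs, data.frame(start = pos, end = blocks$start[b] - 1L,
                                       rate = 1))
      }
      segs <- rbind(segs, data.frame(start = blocks$start[b],
                                     end = blocks$end[b],
                                     rate = blocks$rate[b]))
      pos <- blocks$end[b] + 1L
    }
    if (pos <= seq_length) {
      segs <- rbind(segs, data.frame(start = pos, end = as.integer(seq_length),
                                     rate = 1))
    }
  }
  parts <- lapply(seq_len(nrow(segs)), function(k) {
    sim <- phangorn::simSeq(tree, l = segs$end[k] - segs$start[k] + 1L,
                            type = "DNA", rate = segs$rate[k])
    toupper(as.character(sim))
  })
  mat <- do.call(cbind, parts)
  dna_alignment(mat)
}

#' Plant mislabels among query samples
#'
#' Reassigns the given species of a seeded random
#' `floor(mislabel_fraction * n_queries)` of the query samples to a
#' different ingroup species drawn uniformly; reference samples are never
#' touched.
#'
#' @param truth truth table from [simulate_species_tree()].
#' @param mislabel_fraction fraction of queries to mislabel (in \[0,1)).
#' @param seed integer seed (optional).
#' @return list with `samples` (a sample table whose `species` column holds
#'   the possibly wrong given labels) and `truth` (with
#'   `is_planted_mislabel`).
#' @export
plant_mislabels <- function(truth, mislabel_fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qi <- which(truth$role == "query")
  n_mis <- floor(mislabel_fraction * length(qi))
  pool <- unique(truth$true_species[!truth$outgroup])
  if (n_mis > 0L && length(pool) < 2L) {
    stop("cannot plant mislabels with fewer than 2 species")
  }
  truth$is_planted_mislabel <- FALSE
  if (n_mis > 0L) {
    hit <- sample(qi, n_mis)
    truth$given_species[hit] <- vapply(truth$true_species[hit], function(sp) {
      sample(setdiff(pool, sp), 1L)
    }, character(1L))
    truth$is_planted_mislabel[hit] <- truth$given_species[hit] != truth$true_species[hit]
  }
  samples <- data.frame(sample_id = truth$sample_id,
                        species = truth$given_species,
                        role = truth$role, outgroup = truth$outgroup,
                        stringsAsFactors = FALSE)
  list(samples = as_sample_table(samples), truth = truth)
}

#' Simulate a complete rice-like dataset
#'
#' Chains [simulate_species_tree()], [simulate_alignment()] (plastome-like
#' alignment with hypervariable blocks, plus the configured nuclear-like
#' loci on the same tree) and [plant_mislabels()] with seeds derived from
#' `seed`, so a dataset is fully reproducible from one integer.
#'
#' @param params a `sim_params` object (default [oryza_like_params()]).
#' @param seed integer seed.
#' @return list: `alignment` (plastome-like [dna_alignment]), `nuclear`
#'   (named list of locus alignments), `samples`, `truth`, `tree`,
#'   `params`.
#' @export
simulate_dataset <- function(params = oryza_like_params(), seed = 1L) {
  params <- validate_sim_params(params)
  st <- simulate_species_tree(params, seed = seed)
  aln <- simulate_alignment(st$tree, params$seq_length,
                            blocks = params$hypervariable_blocks,
                            seed = seed + 1L)
  nuclear <- list()
  if (!is.null(params$nuclear_loci) && nrow(params$nuclear_loci)) {
    for (k in seq_len(nrow(params$nuclear_loci))) {
      nuclear[[params$nuclear_loci$name[k]]] <- simulate_alignment(
        st$tree, params$nuclear_loci$length[k],
        blocks = data.frame(start = 1L, end = params$nuclear_loci$length[k],
                            rate = params$nuclear_loci$rate[k]),
        seed = seed + 1L + k)
    }
  }
  pm <- plant_mislabels(st$truth, params$mislabel_fraction,
                        seed = seed + 10L)
  list(alignment = aln, nuclear = nuclear, samples = pm$samples,
       truth = pm$truth, tree = st$tree, species_map = st$species_map,
       params = params)
}
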