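# clade tip-label sets per internal node (index i = node n_tip + i)
clade_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- tree$tip.label
  lapply(pp, function(ix) labs[ix])
}

#' Test a species for supported monophyly
#'
#' A species is monophyletic when some edge bipartition of the tree
#' separates exactly that species' (non-outgroup) samples from all other
#' ingroup samples; outgroup samples may fall on either side. The species
#' counts as resolved when it has a single sample, or when it is
#' monophyletic and the separating edge's bootstrap support exceeds
#' `support_threshold` (strict comparison).
#'
#' @param tree an [ape::phylo] tree with integer bootstrap supports as node
#'   labels (see [bootstrap_tree()]).
#' @param samples sample table (see [read_sample_table()]).
#' @param species_label species to test.
#' @param support_threshold support cutoff, default 75.
#' @return one-row data.frame: `species`, `n_samples`, `is_monophyletic`,
#'   `support`, `resolved`.
#' @export
monophyly_test <- function(tree, samples, species_label,
                           support_threshold = 75) {
  samples <- as_sample_table(samples)
  in_tree <- samples$sample_id %in% tree$tip.label
  ingroup <- samples$sample_id[in_tree & !samples$outgroup]
  sp <- samples$sample_id[in_tree & !samples$outgroup &
                            samples$species == species_label]
  if (!any(samples$species == species_label)) {
    stop("species not in sample table: '", species_label, "'")
  }
  n <- length(sp)
  res <- function(mono, support, resolved) {
    data.frame(species = species_label, n_samples = n,
               is_monophyletic = mono, support = support,
               resolved = resolved, stringsAsFactors = FALSE)
  }
  if (n == 0L) return(res(FALSE, NA_integer_, FALSE))
  if (n == 1L) return(res(TRUE, NA_integer_, TRUE))
  sets <- clade_sets(tree)
  supports <- node_supports(tree)
  # preferred: the species' own stem edge, i.e. the smallest clade whose
  # ingroup content is exactly the species; fallback: a complement-side
  # edge inducing the same bipartition (rooting artefact)
  same <- which(vapply(sets, function(s)
    setequal(intersect(s, ingroup), sp), logical(1L)))
  compl <- which(vapply(sets, function(s)
    setequal(setdiff(ingroup, s), sp), logical(1L)))
  found <- length(same) > 0L || length(compl) > 0L
  best <- NA_integer_
  if (length(same)) {
    sizes <- lengths(sets[same])
    cand <- supports[same[sizes == min(sizes)]]
    if (any(!is.na(cand))) best <- max(cand, na.rm = TRUE)
  } else if (length(compl)) {
    cand <- supports[compl]
    if (any(!is.na(cand))) best <- max(cand, na.rm = TRUE)
  }
  resolved <- found && !is.na(best) && best > support_threshold
  res(found, best, resolved)
}

#' Species-resolution summary for one marker
#'
#' Builds a bootstrap tree over all samples (rooted on the outgroup when
#' present), tests every non-outgroup species for supported monophyly, and
#' tallies aligned length, variable and parsimony-informative sites
#' (outgroups included, as in standard marker reports). Unresolved species
#' are grouped by the smallest supported clade containing all of their
#' samples, exposing which species are entangled.
#'
#' @param aln a [dna_alignment] marker.
#' @param samples sample table covering the alignment ids.
#' @param support_threshold bootstrap cutoff (default 75, strict `>`).
#' @param method tree engine for [bootstrap_tree()]: `"mp"` (default) or
#'   `"nj"`.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed.
#' @param marker_name label used in reports.
#' @param ... passed to [bootstrap_tree()].
#' @return object of class `marker_resolution`: a list with the per-species
#'   table, counts, unresolved groups, and the annotated tree.
#' @export
resolution_summary <- function(aln, samples, support_threshold = 75,
                               method = c("mp", "nj"), n_boot = 200L,
                               seed = NULL, marker_name = "marker", ...) {
  method <- match.arg(method)
  samples <- as_sample_table(samples)
  missing_ids <- setdiff(samples$sample_id, rownames(aln))
  if (length(missing_ids)) stop("samples absent from alignment: ",
                                paste(missing_ids, collapse = ", "))
  aln <- structure(unclass(aln)[samples$sample_id, , drop = FALSE],
                   class = c("dna_alignment", "matrix", "array"))
  og <- samples$sample_id[samples$outgroup]
  tree <- bootstrap_tree(aln, method = method, n_reps = n_boot, seed = seed,
                         outgroup = if (length(og)) og else NULL, ...)
  species <- sort(unique(samples$species[!samples$outgroup]))
  per <- do.call(rbind, lapply(species, function(s) {
    monophyly_test(tree, samples, s, support_threshold)
  }))
  cls <- classify_sites(aln)$class
  unresolved <- per$species[!per$resolved]
  groups <- group_unresolved(tree, samples, unresolved, support_threshold)
  structure(list(
    marker_name = marker_name,
    aligned_length = ncol(aln),
    n_variable = sum(cls %in% c("variable", "parsimony_informative")),
    n_pi_sites = sum(cls == "parsimony_informative"),
    n_species_total = length(species),
    n_species_resolved = sum(per$resolved),
    unresolved_groups = groups,
    per_species = per,
    tree = tree,
    support_threshold = support_threshold
  ), class = "marker_resolution")
}

# Smallest supported clade containing all samples of each unresolved
# species; species sharing that clade form one entangled group.
group_unresolved <- function(tree, samples, unresolved, support_threshold) {
  if (length(unresolved) == 0L) return(list())
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  n_tip <- length(tree$tip.label)
  supports <- node_supports(tree)
  root <- n_tip + 1L
  anchor_node <- vapply(unresolved, function(s) {
    tips <- samples$sample_id[samples$species == s & !samples$outgroup]
    tips <- intersect(tips, tree$tip.label)
    node <- if (length(tips) == 1L) match(tips, tree$tip.label)
            else ape::getMRCA(tree, tips)
    while (node != root) {
      if (node > n_tip) {
        s_sup <- supports[node - n_tip]
        if (!is.na(s_sup) && s_sup > support_threshold) break
      }
      node <- parent[node]
    }
    node
  }, integer(1L))
  unname(split(unresolved, anchor_node))
}

#' @export
print.marker_resolution <- function(x, ...) {
  cat("Marker '", x$marker_name, "': ", x$aligned_length, " aligned sites, ",
      x$n_variable, " variable, ", x$n_pi_sites, " parsimony-informative\n",
      sep = "")
  cat("Species resolved (bootstrap > ", x$support_threshold, "%): ",
      x$n_species_resolved, " / ", x$n_species_total, "\n", sep = "")
  if (length(x$unresolved_groups)) {
    for (g in x$unresolved_groups) {
      cat("  unresolved group: ", paste(g, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Compare discrimination power across markers
#'
#' Runs [resolution_summary()] on each marker and ranks markers by the
#' number of species resolved (ties broken by more parsimony-informative
#' sites).
#'
#' @param markers named list of [dna_alignment] objects over a common
#'   sample set.
#' @param samples sample table.
#' @param ... passed to [resolution_summary()].
#' @return list with `table` (ranked data.frame) and `details` (the
#'   `marker_resolution` objects).
#' @export
compare_markers <- function(markers, samples, ...) {
  if (length(markers) == 0L) stop("no markers")
  if (is.null(names(markers))) names(markers) <- paste0("marker_", seq_along(markers))
  ids <- rownames(markers[[1L]])
  for (k in seq_along(markers)) {
    if (!setequal(rownames(markers[[k]]), ids)) {
      stop("marker '", names(markers)[k], "' has a different id set")
    }
  }
  details <- lapply(seq_along(markers), function(k) {
    resolution_summary(markers[[k]], samples,
                       marker_name = names(markers)[k], ...)
  })
  names(details) <- names(markers)
  tab <- do.call(rbind, lapply(details, function(d) {
    data.frame(marker = d$marker_name, aligned_length = d$aligned_length,
               n_variable = d$n_variable, n_pi_sites = d$n_pi_sites,
               n_species_resolved = d$n_species_resolved,
               n_species_total = d$n_species_total,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$n_species_resolved, -tab$n_pi_sites), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab, details = details)
}
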