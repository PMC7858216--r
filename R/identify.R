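#' Assign query samples to species by clade membership
#'
#' Builds a bootstrap tree over references and queries (rooted on the
#' outgroup when present, else midpoint-rooted), then assigns each query to
#' the species whose reference samples populate the smallest supported
#' clade containing the query: walking from the query tip towards the
#' root, the first clade whose stem support exceeds `support_threshold`
#' and which contains at least one non-outgroup reference decides. If that
#' clade holds references of exactly one species the query is assigned to
#' it; otherwise, or when no such clade exists, the query is
#' `"unresolved"`. A query never gets a guessed label: the verdict is
#' `confirmed` when the assignment matches the given label (modulo
#' synonyms), `mislabeled` when it contradicts it, `unresolved` otherwise.
#'
#' @param aln a [dna_alignment] holding references and queries (and any
#'   outgroups).
#' @param samples sample table; `role` distinguishes `reference` from
#'   `query`, `outgroup` flags rooting taxa.
#' @param method tree engine: `"nj"` (default, fast) or `"mp"`.
#' @param n_boot bootstrap replicates (default 200).
#' @param support_threshold bootstrap cutoff (default 75, strict `>`).
#' @param seed integer seed.
#' @param synonyms optional named character vector mapping species labels
#'   to canonical names (conspecific sets); a query matching a synonym of
#'   its given label is `confirmed`.
#' @param ... passed to [bootstrap_tree()].
#' @return data.frame of class `identification`: `query_id`, `given_label`,
#'   `assigned_label`, `support`, `verdict`; the annotated tree is attached
#'   as attribute `tree`.
#' @export
assign_queries <- function(aln, samples, method = c("nj", "mp"),
                           n_boot = 200L, support_threshold = 75,
                           seed = NULL, synonyms = NULL, ...) {
  method <- match.arg(method)
  samples <- as_sample_table(samples)
  refs <- samples[samples$role == "reference" & !samples$outgroup, ]
  queries <- samples[samples$role == "query", ]
  if (nrow(refs) == 0L) stop("no reference samples")
  missing_ids <- setdiff(samples$sample_id, rownames(aln))
  if (length(missing_ids)) stop("samples absent from alignment: ",
                                paste(missing_ids, collapse = ", "))
  aln <- structure(unclass(aln)[samples$sample_id, , drop = FALSE],
                   class = c("dna_alignment", "matrix", "array"))
  og <- samples$sample_id[samples$outgroup]
  tree <- bootstrap_tree(aln, method = method, n_reps = n_boot, seed = seed,
                         outgroup = if (length(og)) og else NULL, ...)
  if (!length(og)) tree <- phangorn::midpoint(tree)
  canon <- function(x) {
    if (is.null(synonyms)) return(x)
    ifelse(x %in% names(synonyms), unname(synonyms[x]), x)
  }
  n_tip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  supports <- node_supports(tree)
  sets <- clade_sets(tree)
  root <- n_tip + 1L
  ref_species <- stats::setNames(refs$species, refs$sample_id)
  empty <- data.frame(query_id = character(), given_label = character(),
                      assigned_label = character(), support = integer(),
                      verdict = character(), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(queries)), function(k) {
    q <- queries$sample_id[k]
    given <- queries$species[k]
    node <- match(q, tree$tip.label)
    assigned <- "unresolved"
    supp <- NA_integer_
    while (node != root) {
      node <- parent[node]
      if (node == root) break
      s <- supports[node - n_tip]
      if (is.na(s) || s <= support_threshold) next
      clade_refs <- intersect(sets[[node - n_tip]], names(ref_species))
      if (length(clade_refs) == 0L) next
      sp <- unique(canon(ref_species[clade_refs]))
      if (length(sp) == 1L) {
        assigned <- unname(sp)
        supp <- s
      }
      break
    }
    verdict <- if (assigned == "unresolved") "unresolved"
               else if (assigned == canon(given)) "confirmed"
               else "mislabeled"
    data.frame(query_id = q, given_label = given, assigned_label = assigned,
               support = supp, verdict = verdict, stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else empty
  class(res) <- c("identification", "data.frame")
  attr(res, "tree") <- tree
  res
}

#' Summarise mislabel calls
#'
#' @param results an `identification` data.frame from [assign_queries()].
#' @return object of class `mislabel_report`: counts, the mislabel
#'   percentage (integer, half-up rounding), and per-query rows sorted by
#'   verdict then query id.
#' @export
mislabel_report <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no identification results")
  n <- nrow(results)
  n_mis <- sum(results$verdict == "mislabeled")
  ord <- order(factor(results$verdict,
                      levels = c("mislabeled", "unresolved", "confirmed")),
               results$query_id)
  rows <- as.data.frame(results)[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(
    n_queries = n,
    n_mislabeled = n_mis,
    n_confirmed = sum(results$verdict == "confirmed"),
    n_unresolved = sum(results$verdict == "unresolved"),
    percent_mislabeled = floor(100 * n_mis / n + 0.5),
    table = rows
  ), class = "mislabel_report")
}

#' @export
print.mislabel_report <- function(x, ...) {
  cat("Queries: ", x$n_queries, "  mislabeled: ", x$n_mislabeled,
      " (", x$percent_mislabeled, "%)  confirmed: ", x$n_confirmed,
      "  unresolved: ", x$n_unresolved, "\n", sep = "")
  mis <- x$table[x$table$verdict == "mislabeled", , drop = FALSE]
  if (nrow(mis)) {
    for (i in seq_len(nrow(mis))) {
      cat("  ", mis$query_id[i], ": labeled '", mis$given_label[i],
          "', assigned '", mis$assigned_label[i], "' (support ",
          mis$support[i], ")\n", sep = "")
    }
  }
  invisible(x)
}
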