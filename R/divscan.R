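# Per-column state bookkeeping shared by classify_sites, nucleotide_diversity
# and sliding_scan. Only A/C/G/T count as states; gaps and ambiguity codes
# make a column "excluded" under the complete-deletion convention.
column_stats <- function(aln, include_ids = NULL) {
  mat <- subset_rows(aln, include_ids)
  n <- nrow(mat)
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b), numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(NULL, DNA_BASES))
  good <- rowSums(counts)
  excluded <- good < n
  n_states <- rowSums(counts > 0)
  n_major <- rowSums(counts >= 2)
  # pairs of included sequences that differ at each column
  mismatch_pairs <- choose(n, 2) - rowSums(choose(counts, 2))
  list(n = n,
       excluded = excluded,
       n_states = n_states,
       variable = !excluded & n_states >= 2,
       pi_site = !excluded & n_major >= 2 & n_states >= 2,
       mismatch_pairs = mismatch_pairs)
}

subset_rows <- function(aln, include_ids) {
  if (is.null(include_ids)) return(unclass(aln))
  if (length(include_ids) == 0L) stop("empty include set")
  missing_ids <- setdiff(include_ids, rownames(aln))
  if (length(missing_ids)) stop("ids not in alignment: ",
                                paste(missing_ids, collapse = ", "))
  unclass(aln)[include_ids, , drop = FALSE]
}

#' Classify alignment columns
#'
#' Each column is classified as `excluded` (contains a gap or ambiguity code
#' in any included sequence: complete-deletion convention), `invariant`,
#' `variable`, or `parsimony_informative` (at least two states each carried
#' by at least two included sequences; gaps and ambiguity codes never count
#' as states).
#'
#' @param aln a [dna_alignment].
#' @param include_ids optional subset of sequence ids (e.g. to include or
#'   drop outgroups); default all.
#' @return data.frame with `column` (1-based) and `class` (character).
#' @export
classify_sites <- function(aln, include_ids = NULL) {
  st <- column_stats(aln, include_ids)
  cls <- rep("invariant", length(st$excluded))
  cls[st$variable] <- "variable"
  cls[st$pi_site] <- "parsimony_informative"
  cls[st$excluded] <- "excluded"
  data.frame(column = seq_along(cls), class = cls, stringsAsFactors = FALSE)
}

#' Nucleotide diversity over a column span
#'
#' Average per-site pairwise difference:
#' \deqn{\pi = \frac{2}{n(n-1)} \sum_{i<j} d_{ij} / L_{used}}
#' where \eqn{d_{ij}} counts mismatches between sequences i and j over the
#' scored columns and \eqn{L_{used}} counts the columns actually compared.
#' Under `gap_policy = "complete"` any column with a gap or ambiguity in any
#' included sequence is dropped for all pairs; under `"pairwise"` each pair
#' uses its own pair-complete columns and per-pair fractions are averaged.
#' When no column is usable the function returns 0 and sets the attribute
#' `degenerate = TRUE` (with a warning).
#'
#' @param aln a [dna_alignment].
#' @param start,end 1-based inclusive span (default: whole alignment).
#' @param include_ids optional subset of sequence ids.
#' @param gap_policy `"complete"` (default) or `"pairwise"`.
#' @return numeric scalar in \[0, 1\] with attribute `n_sites_used`.
#' @export
nucleotide_diversity <- function(aln, start = 1L, end = aln_length(aln),
                                 include_ids = NULL,
                                 gap_policy = c("complete", "pairwise")) {
  gap_policy <- match.arg(gap_policy)
  sub <- extract_region(aln, start, end)
  mat <- subset_rows(sub, include_ids)
  n <- nrow(mat)
  if (n < 2L) stop("nucleotide diversity needs >= 2 sequences")
  if (gap_policy == "complete") {
    st <- column_stats(sub, include_ids)
    used <- !st$excluded
    L_used <- sum(used)
    if (L_used == 0L) {
      warning("no usable columns in span; returning 0")
      return(structure(0, n_sites_used = 0L, degenerate = TRUE))
    }
    pi <- sum(st$mismatch_pairs[used]) / (choose(n, 2) * L_used)
    return(structure(pi, n_sites_used = L_used))
  }
  # pairwise deletion: per-pair mismatch fraction over pair-complete columns
  definite <- matrix(mat %in% DNA_BASES, nrow = n)
  tot <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- definite[i, ] & definite[j, ]
      if (!any(comp)) next
      tot <- tot + sum(mat[i, comp] != mat[j, comp]) / sum(comp)
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) {
    warning("no comparable pairs in span; returning 0")
    return(structure(0, n_sites_used = 0L, degenerate = TRUE))
  }
  structure(tot / choose(n, 2), n_sites_used = ncol(mat))
}

#' Sliding-window diversity scan
#'
#' Scans the alignment with windows starting at 1, 1+step, 1+2*step, ...;
#' after the last full-length window, one clipped terminal window is added
#' when at least `step` columns remain uncovered. Each window carries
#' nucleotide diversity (complete-deletion) and site-class counts.
#'
#' @param aln a [dna_alignment].
#' @param window_length window size in columns (default 800).
#' @param step offset between window starts (default 100; `step <=
#'   window_length`).
#' @param include_ids optional subset of sequence ids.
#' @return data.frame of class `window_stats`: `start`, `end`, `pi`,
#'   `n_sites_used`, `n_variable`, `n_pi_sites`.
#' @export
sliding_scan <- function(aln, window_length = 800L, step = 100L,
                         include_ids = NULL) {
  L <- aln_length(aln)
  if (step < 1L) stop("step must be >= 1")
  if (window_length < step) stop("window_length must be >= step")
  if (window_length > L) stop("window_length (", window_length,
                              ") exceeds alignment length (", L, ")")
  starts <- seq.int(1L, L - window_length + 1L, by = step)
  ends <- starts + window_length - 1L
  if (max(ends) < L) {
    s <- starts[length(starts)] + step
    if (L - s + 1L >= step) { starts <- c(starts, s); ends <- c(ends, L) }
  }
  st <- column_stats(aln, include_ids)
  n <- st$n
  if (n < 2L) stop("sliding scan needs >= 2 sequences")
  used <- !st$excluded
  # window sums via cumulative sums over per-column quantities
  cs <- function(x) c(0, cumsum(x))
  cum_used <- cs(used)
  cum_mm <- cs(ifelse(used, st$mismatch_pairs, 0))
  cum_var <- cs(st$variable)
  cum_pi <- cs(st$pi_site)
  wsum <- function(cum) cum[ends + 1L] - cum[starts]
  L_used <- wsum(cum_used)
  pi <- ifelse(L_used > 0, wsum(cum_mm) / (choose(n, 2) * L_used), 0)
  out <- data.frame(start = starts, end = ends, pi = pi,
                    n_sites_used = as.integer(L_used),
                    n_variable = as.integer(wsum(cum_var)),
                    n_pi_sites = as.integer(wsum(cum_pi)))
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Select hypervariable regions from scanned windows
#'
#' Windows are ranked by diversity (ties: more variable sites, then leftmost
#' start) and consumed greedily in rank order: a window that overlaps or is
#' directly adjacent to an already-selected region is merged into it
#' (merging may fuse regions); otherwise it founds a new region. Selection
#' stops as soon as `n_candidates` regions of length at least
#' `min_region_length` exist, or the ranked list is exhausted. Windows with
#' zero diversity are never selected. Returned regions are non-overlapping,
#' ranked by mean member-window diversity.
#'
#' @param windows a data.frame from [sliding_scan()].
#' @param n_candidates maximum number of regions to return (default 36).
#' @param min_region_length minimum region span in columns (default 600).
#' @return data.frame with `name`, `start`, `end`, `mean_pi`, `rank`.
#' @export
select_regions <- function(windows, n_candidates = 36L,
                           min_region_length = 600L) {
  if (is.null(windows) || nrow(windows) == 0L) stop("empty window list")
  ord <- order(-windows$pi, -windows$n_variable, windows$start)
  windows <- windows[ord, , drop = FALSE]
  regions <- list()  # each: start, end, pis, nvar
  qualifying <- function() sum(vapply(regions, function(r)
    r$end - r$start + 1L >= min_region_length, logical(1L)))
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    if (w$pi <= 0) break
    touches <- vapply(regions, function(r)
      w$start <= r$end + 1L && w$end >= r$start - 1L, logical(1L))
    if (any(touches)) {
      merged <- regions[touches]
      keep <- regions[!touches]
      r <- list(start = min(w$start, vapply(merged, `[[`, numeric(1L), "start")),
                end = max(w$end, vapply(merged, `[[`, numeric(1L), "end")),
                pis = c(unlist(lapply(merged, `[[`, "pis")), w$pi),
                nvar = sum(vapply(merged, `[[`, numeric(1L), "nvar")) + w$n_variable)
      regions <- c(keep, list(r))
    } else {
      regions <- c(regions, list(list(start = w$start, end = w$end,
                                      pis = w$pi, nvar = w$n_variable)))
    }
    if (qualifying() >= n_candidates) break
  }
  regions <- Filter(function(r) r$end - r$start + 1L >= min_region_length, regions)
  if (length(regions) == 0L) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      mean_pi = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    start = vapply(regions, function(r) as.integer(r$start), integer(1L)),
    end = vapply(regions, function(r) as.integer(r$end), integer(1L)),
    mean_pi = vapply(regions, function(r) mean(r$pis), numeric(1L)),
    nvar = vapply(regions, function(r) as.numeric(r$nvar), numeric(1L)))
  df <- df[order(-df$mean_pi, -df$nvar, df$start), , drop = FALSE]
  df <- utils::head(df, n_candidates)
  df$rank <- seq_len(nrow(df))
  df$name <- paste0("region_", df$rank)
  rownames(df) <- NULL
  df[, c("name", "start", "end", "mean_pi", "rank")]
}
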