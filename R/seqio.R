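# DNA alphabet after normalisation: canonical bases, gap, and IUPAC ambiguity.
DNA_BASES <- c("A", "C", "G", "T")
DNA_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
DNA_ALPHABET <- c(DNA_BASES, "-", DNA_AMBIG)

#' Construct an aligned DNA matrix
#'
#' A `dna_alignment` is a character matrix with one row per sequence and one
#' column per alignment site, rownames holding unique sequence ids, and all
#' characters drawn from \{A,C,G,T,-\} plus the IUPAC ambiguity codes.
#' All coordinates in this package are 1-based and inclusive.
#'
#' @param mat character matrix (rows = sequences) or named character vector of
#'   equal-length strings.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(mat) {
  if (is.character(mat) && !is.matrix(mat)) {
    ids <- names(mat)
    if (is.null(ids)) stop("sequences must be named")
    lens <- nchar(mat)
    if (length(unique(lens)) != 1L) {
      bad <- ids[which(lens != lens[1L])[1L]]
      stop("ragged alignment: sequence '", bad, "' has length ", lens[ids == bad][1L],
           ", expected ", lens[1L])
    }
    mat <- do.call(rbind, strsplit(mat, "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (!is.matrix(mat) || !is.character(mat)) stop("'mat' must be a character matrix")
  if (is.null(rownames(mat))) stop("alignment rows must be named by sequence id")
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate sequence id: ", rownames(mat)[duplicated(rownames(mat))][1L])
  }
  if (ncol(mat) < 1L || nrow(mat) < 1L) stop("empty alignment")
  mat <- normalize_dna(mat)
  structure(mat, class = c("dna_alignment", class(mat)))
}

# uppercase, U->T, ?->N, then validate against the IUPAC alphabet
normalize_dna <- function(mat) {
  mat[] <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat[mat == "?"] <- "N"
  bad <- matrix(!(mat %in% DNA_ALPHABET), nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("illegal character '", mat[idx[1L], idx[2L]], "' in sequence '",
         rownames(mat)[idx[1L]], "' at column ", idx[2L])
  }
  mat
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment: ", nrow(x), " sequences, ", ncol(x), " columns\n", sep = "")
  n <- min(nrow(x), 6L)
  w <- min(ncol(x), 60L)
  for (i in seq_len(n)) {
    cat(format(rownames(x)[i], width = 18L), " ",
        paste(x[i, seq_len(w)], collapse = ""),
        if (ncol(x) > w) "..." else "", "\n", sep = "")
  }
  if (nrow(x) > n) cat("  ... and ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' @export
aln_ids <- function(aln) rownames(aln)

#' @export
aln_length <- function(aln) ncol(aln)

#' Read an aligned FASTA file
#'
#' Sequences are uppercased; `U` is normalised to `T` and `?` to `N`.
#' Ragged records, empty files and characters outside the IUPAC DNA
#' alphabet are hard errors naming the offending record.
#'
#' @param path path to an aligned FASTA file.
#' @return a [dna_alignment], in file order.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  lens <- lengths(recs)
  if (any(lens == 0L)) stop("empty sequence: '", names(recs)[lens == 0L][1L], "'")
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("ragged alignment: sequence '", names(recs)[bad], "' has length ",
         lens[bad], ", expected ", lens[1L])
  }
  mat <- do.call(rbind, lapply(recs, unname))
  rownames(mat) <- names(recs)
  dna_alignment(mat)
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a sample table
#'
#' Tab-separated with a header; required column `sample_id` and `species`,
#' optional `role` (`reference` or `query`; defaults to reference) and
#' `outgroup` (logical; defaults to FALSE).
#'
#' @param path path to a TSV file.
#' @return a data.frame with columns `sample_id`, `species`, `role`,
#'   `outgroup`.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_sample_table(tab)
}

#' Validate / coerce a data.frame into a sample table
#'
#' @param tab data.frame with at least `sample_id` and `species`.
#' @return validated data.frame with `sample_id`, `species`, `role`,
#'   `outgroup`.
#' @export
as_sample_table <- function(tab) {
  need <- c("sample_id", "species")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ", tab$sample_id[duplicated(tab$sample_id)][1L])
  }
  if (is.null(tab$role)) tab$role <- "reference"
  tab$role[is.na(tab$role) | tab$role == ""] <- "reference"
  bad <- setdiff(unique(tab$role), c("reference", "query"))
  if (length(bad)) stop("unknown role token: '", bad[1L], "'")
  if (is.null(tab$outgroup)) tab$outgroup <- FALSE
  tab$outgroup <- parse_flag(tab$outgroup)
  tab[, c("sample_id", "species", "role", "outgroup")]
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  out <- x %in% c("true", "t", "1", "yes", "y")
  out
}

#' Write a sample table to TSV
#' @param tab sample table data.frame.
#' @param path output path.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a column span from an alignment
#'
#' @param aln a [dna_alignment].
#' @param start,end 1-based inclusive column range.
#' @return a [dna_alignment] of length `end - start + 1`.
#' @export
extract_region <- function(aln, start, end) {
  if (start < 1L || end > ncol(aln) || start > end) {
    stop("region [", start, ", ", end, "] out of range for alignment of length ",
         ncol(aln))
  }
  sub <- aln[, start:end, drop = FALSE]
  structure(sub, class = class(aln))
}

#' Concatenate marker alignments sharing a sample set
#'
#' Rows are joined on sequence id (the order of the first alignment wins);
#' the returned partition map records each marker's span in the
#' concatenation, 1-based inclusive.
#'
#' @param alns list of [dna_alignment] objects over identical id sets.
#' @param names optional marker names (defaults to list names or `marker_i`).
#' @return list with elements `alignment` and `partition` (data.frame with
#'   `marker`, `start`, `end`).
#' @export
concatenate_alignments <- function(alns, names = NULL) {
  if (length(alns) == 0L) stop("no alignments to concatenate")
  if (is.null(names)) names <- base::names(alns)
  if (is.null(names)) names <- paste0("marker_", seq_along(alns))
  ids <- rownames(alns[[1L]])
  for (k in seq_along(alns)) {
    missing_ids <- setdiff(ids, rownames(alns[[k]]))
    extra <- setdiff(rownames(alns[[k]]), ids)
    if (length(missing_ids) || length(extra)) {
      stop("id sets differ in '", names[k], "': missing [",
           paste(missing_ids, collapse = ", "), "], extra [",
           paste(extra, collapse = ", "), "]")
    }
  }
  mats <- lapply(alns, function(a) a[ids, , drop = FALSE])
  lens <- vapply(mats, ncol, integer(1L))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- do.call(cbind, mats)
  rownames(out) <- ids
  list(alignment = dna_alignment(out),
       partition = data.frame(marker = names, start = starts, end = ends,
                              stringsAsFactors = FALSE))
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that keep
#' integer bootstrap supports as internal node labels and round branch
#' lengths to six decimals on output.
#'
#' @param path file path.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick in ", path)
  if (is.null(tr$Nnode) || length(tr$tip.label) < 2L) stop("malformed Newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree (supports, if any, as node labels).
#' @export
write_newick <- function(tree, path) {
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  if (!is.null(tree$edge.length)) tree$edge.length <- round(tree$edge.length, 6L)
  ape::write.tree(tree, file = path)
  invisible(path)
}
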