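#' @useDynLib coevcomplex, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim setNames quantile
#' @importFrom utils read.delim write.table head
NULL

#' Amino-acid alphabet used throughout the package
#'
#' Twenty standard amino acids plus the gap character, in the conventional
#' coupling-analysis ordering. The gap is treated as a 21st state; ambiguous
#' or nonstandard letters (B, Z, X, U, O, J) are mapped to the gap state on
#' input.
#'
#' @format Character vector of length 21.
#' @export
msa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "-")

GAP_STATE <- 21L

#' Construct a multiple sequence alignment object
#'
#' Low-level constructor for the `msa` class: a rectangular character matrix
#' over the 21-letter alphabet (see [msa_alphabet]) with sequence
#' identifiers, an optional query row, and a mapping from retained columns
#' to 1-based positions in the ungapped query sequence.
#'
#' @param seqs Character matrix of single characters (rows = sequences).
#' @param ids Character vector of sequence identifiers, one per row.
#' @param query Integer row index of the query/reference sequence, or
#'   `NA` if the alignment has no designated query.
#' @param colmap Integer vector mapping columns to query positions
#'   (`NA` entries where the query carries a gap).
#' @return An object of class `msa`.
#' @export
msa <- function(seqs, ids, query = NA_integer_,
                colmap = seq_len(ncol(seqs))) {
  stopifnot(is.matrix(seqs), is.character(seqs))
  if (length(ids) != nrow(seqs))
    stop("ids must have one entry per alignment row")
  if (length(colmap) != ncol(seqs))
    stop("colmap must have one entry per alignment column")
  seqs <- normalize_alphabet(seqs)
  if (!is.na(query)) {
    if (query < 1L || query > nrow(seqs)) stop("query row out of range")
  }
  structure(list(ids = as.character(ids), seqs = seqs,
                 query = as.integer(query), colmap = as.integer(colmap)),
            class = "msa")
}

# Uppercase, map '.' to '-' and any letter outside the 20 standard amino
# acids to the gap state.
normalize_alphabet <- function(seqs) {
  seqs[] <- toupper(seqs)
  seqs[seqs == "."] <- "-"
  seqs[!(seqs %in% msa_alphabet)] <- "-"
  seqs
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  if (!is.na(x$query))
    cat(sprintf("  query: row %d (%s)\n", x$query, x$ids[x$query]))
  cat(sprintf("  gap fraction: %.3f\n", mean(x$seqs == "-")))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$seqs)

#' Read a multiple sequence alignment from FASTA or A3M
#'
#' FASTA records must all have the same aligned length. In A3M format,
#' lowercase letters denote insertion states relative to the query and are
#' removed, after which all rows must be rectangular. Nonstandard residue
#' letters are mapped to the gap state.
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"a3m"`. `"auto"` treats files
#'   with extension `.a3m` as A3M and everything else as FASTA.
#' @param query Row index of the query sequence (by convention the first
#'   record, as produced by homology-search pipelines).
#' @return An [msa] object. Row order of the input is preserved.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a3m"),
                           query = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("failed to parse '%s' as FASTA: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) stop(sprintf("no sequences in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  strs <- as.character(set)
  if (format == "a3m")
    strs <- gsub("[a-z]", "", strs)
  lens <- nchar(strs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf(
      "alignment is not rectangular: sequence '%s' has length %d, expected %d",
      ids[bad], lens[bad], lens[1L]))
  }
  seqs <- matrix(unlist(strsplit(strs, "", fixed = TRUE), use.names = FALSE),
                 nrow = length(strs), byrow = TRUE)
  msa(seqs, ids, query = query)
}

#' Write an alignment to FASTA
#'
#' @param aln An [msa] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(apply(aln$seqs, 1L, paste, collapse = ""))
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Restrict an alignment to query columns
#'
#' Drops columns at which the query sequence carries a gap, so that every
#' retained column corresponds to a residue of the query; the column map is
#' set to the 1-based query residue numbering.
#'
#' @param aln An [msa] object with a designated query row.
#' @return An [msa] whose query row is gap-free.
#' @export
map_to_query <- function(aln) {
  if (is.na(aln$query)) stop("alignment has no designated query row")
  qrow <- aln$seqs[aln$query, ]
  keep <- qrow != "-"
  if (!any(keep)) stop("query sequence is all gaps")
  msa(aln$seqs[, keep, drop = FALSE], aln$ids, query = aln$query,
      colmap = cumsum(keep)[keep])
}

encode_msa <- function(aln) {
  m <- matrix(match(aln$seqs, msa_alphabet), nrow = nrow(aln$seqs))
  storage.mode(m) <- "integer"
  m
}

#' Greedy redundancy filter
#'
#' Scans rows in input order (query row, when present, is always examined
#' and kept first) and keeps a row iff its fractional identity to every
#' previously kept row is at most `max_identity`. Identity is the number of
#' matching columns divided by the number of columns where neither row is a
#' gap (0 if there is no such column).
#'
#' @param aln An [msa] or [paired_msa] object.
#' @param max_identity Maximum allowed pairwise identity among kept rows.
#' @return The filtered alignment, original row order preserved.
#' @export
filter_redundancy <- function(aln, max_identity = 0.90) {
  n <- nrow(aln$seqs)
  if (n == 0L) stop("alignment is empty")
  ord <- seq_len(n)
  if (!is.na(aln$query)) ord <- c(aln$query, ord[-aln$query])
  keep <- greedy_redundancy_cpp(encode_msa(aln), GAP_STATE, max_identity,
                                as.integer(ord - 1L))
  subset_msa_rows(aln, which(keep))
}

#' Remove gap-rich columns
#'
#' Drops every column whose gap fraction strictly exceeds `max_gap_frac`
#' and updates the column map accordingly.
#'
#' @param aln An [msa] or [paired_msa] object.
#' @param max_gap_frac Columns with gap fraction greater than this are
#'   removed (a column at exactly the threshold is retained).
#' @return The column-filtered alignment.
#' @export
remove_gappy_columns <- function(aln, max_gap_frac = 0.75) {
  if (nrow(aln$seqs) == 0L) stop("alignment is empty")
  gapfrac <- colMeans(aln$seqs == "-")
  keep <- gapfrac <= max_gap_frac
  if (!any(keep)) stop("all columns exceed the gap-fraction threshold")
  subset_msa_cols(aln, which(keep))
}

#' Position-based sequence weights
#'
#' Weight of a row is the reciprocal of the number of rows (including
#' itself) with fractional identity at or above `identity_threshold` to it.
#' The sum of the weights is the effective sequence count `neff`.
#'
#' @param aln An [msa] or [paired_msa] object.
#' @param identity_threshold Identity level at or above which two rows are
#'   counted as redundant.
#' @return An object of class `seq_weights`: numeric vector of per-row
#'   weights in (0, 1] with attribute `neff`.
#' @export
sequence_weights <- function(aln, identity_threshold = 0.80) {
  if (nrow(aln$seqs) == 0L) stop("alignment is empty")
  w <- seq_weights_cpp(encode_msa(aln), GAP_STATE, identity_threshold)
  structure(w, neff = sum(w), class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("Sequence weights: %d rows, Neff = %.2f\n",
              length(x), attr(x, "neff")))
  invisible(x)
}

#' Alignment summary statistics
#'
#' @param aln An [msa] object.
#' @param path Optional path; when given, the one-row summary is written as
#'   TSV.
#' @return A data frame with row/column counts and gap statistics.
#' @export
alignment_summary <- function(aln, path = NULL) {
  gf <- colMeans(aln$seqs == "-")
  out <- data.frame(
    n_sequences = nrow(aln$seqs),
    n_columns = ncol(aln$seqs),
    gap_fraction = mean(aln$seqs == "-"),
    max_column_gap_fraction = max(gf),
    median_column_gap_fraction = stats::median(gf)
  )
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

# ---- internal subsetting that keeps msa/paired_msa metadata coherent ----

subset_msa_rows <- function(aln, rows) {
  query <- aln$query
  if (!is.na(query)) {
    pos <- match(query, rows)
    query <- if (is.na(pos)) NA_integer_ else pos
  }
  out <- msa(aln$seqs[rows, , drop = FALSE], aln$ids[rows], query = query,
             colmap = aln$colmap)
  if (inherits(aln, "paired_msa")) {
    out <- as_paired_msa(out, boundary = aln$boundary,
                         genome_ids = aln$genome_ids[rows],
                         source = aln$source[rows, , drop = FALSE],
                         colmap_a = aln$colmap_a, colmap_b = aln$colmap_b)
  }
  out
}

subset_msa_cols <- function(aln, cols) {
  out <- msa(aln$seqs[, cols, drop = FALSE], aln$ids, query = aln$query,
             colmap = aln$colmap[cols])
  if (inherits(aln, "paired_msa")) {
    p <- aln$boundary
    in_a <- cols <= p
    if (!any(in_a) || all(in_a))
      stop("column filtering removed one protein entirely")
    out <- as_paired_msa(out, boundary = sum(in_a),
                         genome_ids = aln$genome_ids, source = aln$source,
                         colmap_a = aln$colmap_a[cols[in_a]],
                         colmap_b = aln$colmap_b[cols[!in_a] - p])
  }
  out
}
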