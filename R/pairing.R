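#' Construct a paired alignment object
#'
#' A paired alignment concatenates, row by row, sequences of two protein
#' families drawn from the same genome: columns `1..p` belong to protein A
#' and columns `p+1..p+q` to protein B.
#'
#' @param aln An [msa] over the concatenated columns.
#' @param boundary Integer `p`, the last column belonging to protein A.
#' @param genome_ids Character vector, genome of origin per row.
#' @param source Data frame with one row per alignment row giving
#'   `genome_id`, `row_a`, `row_b` (source rows in the family alignments).
#' @param colmap_a,colmap_b Query-position maps for the two halves.
#' @return An object of class `c("paired_msa", "msa")`.
#' @export
as_paired_msa <- function(aln, boundary, genome_ids, source = NULL,
                          colmap_a = seq_len(boundary),
                          colmap_b = seq_len(ncol(aln$seqs) - boundary)) {
  L <- ncol(aln$seqs)
  if (boundary < 1L || boundary >= L)
    stop("boundary must satisfy 1 <= p < total columns")
  if (length(genome_ids) != nrow(aln$seqs))
    stop("genome_ids must have one entry per row")
  if (is.null(source))
    source <- data.frame(genome_id = genome_ids,
                         row_a = NA_integer_, row_b = NA_integer_)
  aln$boundary <- as.integer(boundary)
  aln$genome_ids <- as.character(genome_ids)
  aln$source <- source
  aln$colmap_a <- as.integer(colmap_a)
  aln$colmap_b <- as.integer(colmap_b)
  class(aln) <- c("paired_msa", "msa")
  aln
}

#' @export
print.paired_msa <- function(x, ...) {
  cat(sprintf(
    "Paired alignment: %d rows, %d + %d columns (boundary p = %d)\n",
    nrow(x$seqs), x$boundary, ncol(x$seqs) - x$boundary, x$boundary))
  cat(sprintf("  genomes: %d unique\n", length(unique(x$genome_ids))))
  invisible(x)
}

#' Validate a table of gene records
#'
#' Gene records map genomes to gene annotations for one protein family:
#' `genome_id`, serial `accession_index` (a proxy for gene order on the
#' genome), `family_id`, and `sequence_id` naming the corresponding row of
#' the family alignment.
#'
#' @param records Data frame with the four columns above.
#' @return The validated data frame.
#' @export
gene_records <- function(records) {
  need <- c("genome_id", "accession_index", "family_id", "sequence_id")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("gene records missing column(s): ", paste(miss, collapse = ", "))
  records$accession_index <- as.integer(records$accession_index)
  if (any(records$accession_index < 0L))
    stop("accession_index must be non-negative")
  key <- paste(records$genome_id, records$accession_index)
  if (anyDuplicated(key))
    stop("(genome_id, accession_index) must be unique within a family")
  records
}

#' Read gene records from TSV
#'
#' @param path TSV file with columns `genome_id`, `accession_index`,
#'   `family_id`, `sequence_id`.
#' @return Validated gene-record data frame.
#' @export
read_gene_records <- function(path) {
  gene_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Number of annotated genes between two genes
#'
#' For two genes of the same genome with serial accession indices `ia` and
#' `ib`, the intergenic distance is `|ia - ib| - 1` (the count of annotated
#' genes lying between them), floored at zero.
#'
#' @param a,b Single gene records (lists or one-row data frames with
#'   `genome_id` and `accession_index`).
#' @param same_gene What to do when both records have the same accession
#'   index: `"error"` (default; the records denote the same gene) or
#'   `"zero"`.
#' @return Integer gene count.
#' @export
delta_gene <- function(a, b, same_gene = c("error", "zero")) {
  same_gene <- match.arg(same_gene)
  if (a$genome_id != b$genome_id)
    stop("delta_gene is only defined within one genome")
  d <- abs(a$accession_index - b$accession_index)
  if (d == 0L) {
    if (same_gene == "error")
      stop("records have identical accession indices (same gene)")
    return(0L)
  }
  as.integer(max(d - 1L, 0L))
}

#' Test conservation of an intergenic distance across genomes
#'
#' Given one intergenic distance per genome, the modal distance `M` is
#' accepted, together with the second or third most common distance when it
#' lies within 1 of `M` (allowing for annotation ambiguity). The pair of
#' families passes when the fraction of genomes whose distance falls in the
#' accepted set reaches `min_conservation` and `M < max_delta`. Ties for the
#' mode are broken toward the smaller distance.
#'
#' @param deltas Integer vector of per-genome intergenic distances.
#' @param min_conservation Required fraction of genomes in the accepted set.
#' @param max_delta The modal distance must be strictly below this.
#' @return List with elements `pass`, `accepted` (integer set), `mode`,
#'   `conservation`, and the distance histogram `table`.
#' @export
conserved_pair_test <- function(deltas, min_conservation = 0.60,
                                max_delta = 20L) {
  if (length(deltas) == 0L) stop("no intergenic distances supplied")
  deltas <- as.integer(deltas)
  tab <- table(deltas)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  ord <- order(-cnt, vals)   # most common first, ties toward smaller delta
  vals <- vals[ord]
  cnt <- cnt[ord]
  mode <- vals[1L]
  accepted <- mode
  for (k in 2:3) {
    if (k <= length(vals) && abs(vals[k] - mode) <= 1L)
      accepted <- c(accepted, vals[k])
  }
  conservation <- mean(deltas %in% accepted)
  list(pass = conservation >= min_conservation && mode < max_delta,
       accepted = sort(accepted), mode = mode,
       conservation = conservation, table = tab)
}

#' Build a paired alignment from two families via the intergenic-distance rule
#'
#' For every genome containing members of both families, all candidate
#' (A, B) gene pairs are formed and the pair with the smallest intergenic
#' distance is taken as that genome's candidate. The candidate distances are
#' then subjected to [conserved_pair_test]; rows are concatenated only for
#' genomes whose distance lies in the accepted set. The result is passed
#' through [remove_gappy_columns] and [filter_redundancy].
#'
#' @param aln_a,aln_b Query-mapped family alignments ([msa]).
#' @param records_a,records_b Gene-record tables (see [gene_records]) whose
#'   `sequence_id` values name rows of the corresponding alignment.
#' @param min_conservation,max_delta Passed to [conserved_pair_test].
#' @param max_identity Redundancy threshold for the paired alignment.
#' @param max_gap_frac Column gap-fraction threshold for the paired
#'   alignment.
#' @return A [as_paired_msa()] object. The returned object records, per row,
#'   the genome and the source rows in the two family alignments.
#' @export
build_paired_alignment <- function(aln_a, aln_b, records_a, records_b,
                                   min_conservation = 0.60, max_delta = 20L,
                                   max_identity = 0.90,
                                   max_gap_frac = 0.75) {
  records_a <- gene_records(records_a)
  records_b <- gene_records(records_b)
  records_a$row <- match(records_a$sequence_id, aln_a$ids)
  records_b$row <- match(records_b$sequence_id, aln_b$ids)
  if (anyNA(records_a$row) || anyNA(records_b$row))
    stop("gene records reference sequence ids absent from the alignments")

  genomes <- sort(intersect(unique(records_a$genome_id),
                            unique(records_b$genome_id)))
  if (length(genomes) == 0L)
    stop("the two families share no genome")

  best <- lapply(genomes, function(g) {
    ra <- records_a[records_a$genome_id == g, , drop = FALSE]
    rb <- records_b[records_b$genome_id == g, , drop = FALSE]
    cand <- expand.grid(a = seq_len(nrow(ra)), b = seq_len(nrow(rb)))
    ia <- ra$accession_index[cand$a]
    ib <- rb$accession_index[cand$b]
    d <- abs(ia - ib) - 1L
    ok <- abs(ia - ib) > 0L          # identical indices denote the same gene
    if (!any(ok)) return(NULL)
    d <- pmax(d[ok], 0L)
    cand <- cand[ok, , drop = FALSE]
    # minimum-distance pair; deterministic tie-break on accession indices
    ord <- order(d, ia[ok], ib[ok])
    pick <- ord[1L]
    data.frame(genome_id = g, delta = d[pick],
               row_a = ra$row[cand$a[pick]], row_b = rb$row[cand$b[pick]],
               stringsAsFactors = FALSE)
  })
  best <- do.call(rbind, best)
  if (is.null(best) || nrow(best) == 0L)
    stop("no genome yields a candidate gene pair")

  test <- conserved_pair_test(best$delta, min_conservation, max_delta)
  if (!test$pass) {
    hist <- paste(sprintf("delta=%s: %d", names(test$table),
                          as.integer(test$table)), collapse = ", ")
    stop(sprintf(paste0(
      "no conserved intergenic distance (mode %d, conservation %.2f over ",
      "%d genomes); distance histogram: %s"),
      test$mode, test$conservation, nrow(best), hist))
  }
  sel <- best[best$delta %in% test$accepted, , drop = FALSE]

  seqs <- cbind(aln_a$seqs[sel$row_a, , drop = FALSE],
                aln_b$seqs[sel$row_b, , drop = FALSE])
  ids <- sprintf("%s|%s|%s", sel$genome_id, aln_a$ids[sel$row_a],
                 aln_b$ids[sel$row_b])
  paln <- as_paired_msa(
    msa(seqs, ids, query = NA_integer_),
    boundary = ncol(aln_a$seqs), genome_ids = sel$genome_id,
    source = data.frame(genome_id = sel$genome_id, row_a = sel$row_a,
                        row_b = sel$row_b, stringsAsFactors = FALSE),
    colmap_a = aln_a$colmap, colmap_b = aln_b$colmap)
  paln <- remove_gappy_columns(paln, max_gap_frac)
  filter_redundancy(paln, max_identity)
}

#' Write a paired alignment as FASTA plus a JSON sidecar
#'
#' The FASTA headers are `genome|idA|idB`; the sidecar (at
#' `paste0(path, ".json")`) records the boundary `p` and the query-position
#' maps of the two halves.
#'
#' @param paln A [as_paired_msa()] object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_paired_alignment <- function(paln, path) {
  write_alignment(paln, path)
  meta <- list(boundary = paln$boundary,
               n_rows = nrow(paln$seqs),
               genome_ids = paln$genome_ids,
               colmap_a = paln$colmap_a,
               colmap_b = paln$colmap_b)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a paired alignment written by [write_paired_alignment]
#'
#' @param path FASTA path (the sidecar `paste0(path, ".json")` must exist).
#' @return A [as_paired_msa()] object.
#' @export
read_paired_alignment <- function(path) {
  aln <- read_alignment(path, format = "fasta", query = 1L)
  aln$query <- NA_integer_
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  as_paired_msa(aln, boundary = meta$boundary, genome_ids = meta$genome_ids,
                colmap_a = meta$colmap_a, colmap_b = meta$colmap_b)
}
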