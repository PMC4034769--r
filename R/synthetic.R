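#' Specification of a synthetic protein complex with planted contacts
#'
#' Describes a Potts model over a paired alignment of lengths `p + q` with
#' couplings planted on chosen inter-protein position pairs, from which
#' sequences are Gibbs-sampled. Planted couplings are state-matching: the
#' 20 amino-acid diagonal entries of the 21 x 21 coupling matrix are set to
#' `coupling`, all other entries zero. Fields are i.i.d. normal with sd
#' `field_sd` over the amino-acid states; the gap state is given a strongly
#' negative field so sampled sequences are ungapped, as in a
#' redundancy-filtered, query-mapped real alignment.
#'
#' @param p,q Lengths of proteins A and B.
#' @param contacts Data frame with columns `i`, `j` (`i <= p < j`), or
#'   `NULL` to plant `n_contacts` pairs at random when sampling.
#' @param n_contacts Number of pairs to plant when `contacts` is `NULL`.
#' @param coupling Magnitude of the planted state-matching coupling
#'   (typical detectable range 0.5-2).
#' @param field_sd Standard deviation of the random fields (0 = uniform).
#' @param n_seq Number of sequences to sample.
#' @param burnin Gibbs burn-in sweeps; default `100 * (p + q)`.
#' @param thin Sweeps between kept sequences.
#' @param seed Seed for reproducibility.
#' @return Object of class `planted_complex_spec`.
#' @export
planted_complex_spec <- function(p = 25L, q = 25L, contacts = NULL,
                                 n_contacts = 10L, coupling = 1.0,
                                 field_sd = 0, n_seq = 5000L,
                                 burnin = NULL, thin = 10L, seed = NULL) {
  L <- p + q
  if (!is.null(contacts)) {
    stopifnot(all(contacts$i >= 1L), all(contacts$i <= p),
              all(contacts$j > p), all(contacts$j <= L))
  }
  if (n_seq <= 0L) stop("n_seq must be positive")
  if (is.null(burnin)) burnin <- 100L * L
  structure(list(p = as.integer(p), q = as.integer(q), contacts = contacts,
                 n_contacts = as.integer(n_contacts), coupling = coupling,
                 field_sd = field_sd, n_seq = as.integer(n_seq),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = seed),
            class = "planted_complex_spec")
}

#' Gibbs-sample a paired alignment from a planted Potts model
#'
#' Samples `n_seq` paired sequences from the global Potts distribution
#' described by `spec` using a single-chain Gibbs sampler (burn-in, then
#' one sequence kept every `thin` sweeps). Deterministic given `spec$seed`.
#'
#' @param spec A [planted_complex_spec].
#' @return List with `alignment` (a [as_paired_msa()]) and `truth` (the
#'   planted contact pairs, coupling magnitude, and generating fields).
#' @export
sample_potts <- function(spec) {
  stopifnot(inherits(spec, "planted_complex_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  p <- spec$p
  L <- spec$p + spec$q
  A <- 21L

  contacts <- spec$contacts
  if (is.null(contacts)) {
    i <- sample.int(p, spec$n_contacts, replace = TRUE)
    j <- p + sample.int(spec$q, spec$n_contacts, replace = TRUE)
    key <- unique(paste(i, j))
    while (length(key) < spec$n_contacts) {
      i2 <- sample.int(p, 1L)
      j2 <- p + sample.int(spec$q, 1L)
      key <- unique(c(key, paste(i2, j2)))
    }
    parts <- do.call(rbind, strsplit(key, " "))
    contacts <- data.frame(i = as.integer(parts[, 1L]),
                           j = as.integer(parts[, 2L]))
  }

  v <- matrix(0, L, A)
  if (spec$field_sd > 0)
    v[, 1:20] <- matrix(stats::rnorm(L * 20L, sd = spec$field_sd), L, 20L)

  npair <- L * (L - 1L) / 2L
  wpacked <- numeric(npair * A * A)
  pair_offset <- function(i, j) {
    # 0-based offset of pair (i < j) in row-major pair order
    ((i - 1L) * (2L * L - i) / 2L + (j - i - 1L)) * A * A
  }
  diag_idx <- (seq_len(20L) - 1L) * A + seq_len(20L)   # row-major (a,a)
  for (k in seq_len(nrow(contacts))) {
    off <- pair_offset(contacts$i[k], contacts$j[k])
    wpacked[off + diag_idx] <- spec$coupling
  }
  Wflat <- expand_coupling_table(wpacked, L, A)

  X <- gibbs_sample_potts(v, Wflat, L, A, 20L, spec$n_seq, spec$burnin,
                          spec$thin)
  seqs <- matrix(msa_alphabet[X], nrow = nrow(X))
  ids <- sprintf("g%05d|synthA|synthB", seq_len(nrow(X)))
  paln <- as_paired_msa(msa(seqs, ids, query = NA_integer_), boundary = p,
                        genome_ids = sprintf("g%05d", seq_len(nrow(X))))
  list(alignment = paln,
       truth = list(contacts = contacts, coupling = spec$coupling,
                    v = v, spec = spec))
}

#' Synthetic operon-structured genome annotations
#'
#' Generates `n_genomes` genomes, each carrying one gene of family A and
#' one of family B. In a `conservation` fraction of genomes the true
#' ortholog pair sits at intergenic distance `planted_delta`; in the rest
#' it sits at a random distant position (`decoy_range`). With probability
#' `paralog_rate` a genome additionally carries a family-B paralog decoy at
#' a random distant locus. Family alignments contain one random ungapped
#' sequence per gene record (uniform over the 20 amino acids, so pairwise
#' identities sit far below the redundancy threshold).
#'
#' @param n_genomes Number of genomes.
#' @param planted_delta Conserved intergenic distance of the true pair.
#' @param conservation Fraction of genomes at the planted distance.
#' @param paralog_rate Per-genome probability of a paralog decoy.
#' @param len_a,len_b Sequence lengths of the two families.
#' @param decoy_range Integer range (inclusive) from which non-conserved
#'   and paralog intergenic distances are drawn; the default 25..60 lies
#'   safely above the distance bound and outside mode +/- 1.
#' @param seed Seed for reproducibility.
#' @return List with `records` (family gene-record tables), `alignments`
#'   (family [msa]s), and `truth` (per-genome true pair with its distance
#'   and a `conserved` flag).
#' @export
make_genomes <- function(n_genomes = 50L, planted_delta = 3L,
                         conservation = 0.7, paralog_rate = 0.3,
                         len_a = 30L, len_b = 30L,
                         decoy_range = c(25L, 60L), seed = NULL) {
  if (conservation <= 0 || conservation > 1)
    stop("conservation must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_cons <- round(conservation * n_genomes)
  conserved <- rep(c(TRUE, FALSE), c(n_cons, n_genomes - n_cons))

  rand_delta <- function(n)
    sample(seq(decoy_range[1L], decoy_range[2L]), n, replace = TRUE)

  genomes <- sprintf("genome%03d", seq_len(n_genomes))
  ia <- sample(100:5000, n_genomes)
  delta <- ifelse(conserved, planted_delta, rand_delta(n_genomes))
  ib <- ia + delta + 1L

  rec_a <- data.frame(genome_id = genomes, accession_index = ia,
                      family_id = "famA",
                      sequence_id = paste0(genomes, "_A"),
                      stringsAsFactors = FALSE)
  rec_b <- data.frame(genome_id = genomes, accession_index = ib,
                      family_id = "famB",
                      sequence_id = paste0(genomes, "_B"),
                      stringsAsFactors = FALSE)

  has_paralog <- stats::runif(n_genomes) < paralog_rate
  if (any(has_paralog)) {
    pg <- which(has_paralog)
    ip <- ia[pg] + rand_delta(length(pg)) + 1L
    clash <- ip == ib[pg]
    ip[clash] <- ip[clash] + 2L
    rec_b <- rbind(rec_b, data.frame(
      genome_id = genomes[pg], accession_index = ip, family_id = "famB",
      sequence_id = paste0(genomes[pg], "_Bpara"), stringsAsFactors = FALSE))
  }

  rand_aln <- function(ids, len) {
    seqs <- matrix(sample(msa_alphabet[1:20], length(ids) * len,
                          replace = TRUE), nrow = length(ids))
    msa(seqs, ids, query = NA_integer_)
  }
  list(records = list(A = gene_records(rec_a), B = gene_records(rec_b)),
       alignments = list(A = rand_aln(rec_a$sequence_id, len_a),
                         B = rand_aln(rec_b$sequence_id, len_b)),
       truth = data.frame(genome_id = genomes,
                          id_a = rec_a$sequence_id[seq_len(n_genomes)],
                          id_b = paste0(genomes, "_B"),
                          delta = delta, conserved = conserved,
                          stringsAsFactors = FALSE))
}

#' Idealized two-chain structure with planted contacts
#'
#' Builds two poly-alanine chains (N, CA, C, O, CB per residue) laid out on
#' a regular grid: chain A along x with side chains pointing toward chain
#' B, chain B at `separation` Angstrom. For every requested contact
#' `(res_a, res_b, distance)` the chain-B residue is relocated so its
#' Cbeta sits exactly `distance` Angstrom from the chain-A Cbeta; all other
#' cross-chain residue pairs remain at least `separation - 4` apart. Fully
#' deterministic.
#'
#' @param len_a,len_b Residues per chain.
#' @param contacts Data frame with columns `res_a`, `res_b`, `distance`
#'   (Angstrom); may be empty.
#' @param separation Baseline inter-chain distance (Angstrom).
#' @return A [structure_model] with chains `"A"` and `"B"`.
#' @export
make_toy_structure <- function(len_a = 10L, len_b = 10L,
                               contacts = NULL, separation = 50) {
  if (is.null(contacts))
    contacts <- data.frame(res_a = integer(0), res_b = integer(0),
                           distance = numeric(0))
  if (nrow(contacts)) {
    stopifnot(all(contacts$res_a >= 1L), all(contacts$res_a <= len_a),
              all(contacts$res_b >= 1L), all(contacts$res_b <= len_b))
    if (anyDuplicated(contacts$res_b))
      stop("infeasible geometry: one chain-B residue in several contacts")
    if (any(contacts$distance >= separation))
      stop("infeasible geometry: contact distance exceeds the separation")
  }

  residue <- function(chain, resno, cb_x, cb_y, up) {
    # up = +1: backbone above the Cbeta (chain B); -1: below (chain A)
    data.frame(chain = chain, resno = resno, resid = "ALA",
               elety = c("N", "CA", "C", "O", "CB"),
               x = c(cb_x - 1.2, cb_x, cb_x + 1.2, cb_x + 1.9, cb_x),
               y = cb_y + up * c(2.2, 1.5, 2.2, 1.7, 0),
               z = 0, stringsAsFactors = FALSE)
  }

  spacing <- 4
  rows <- lapply(seq_len(len_a), function(r)
    residue("A", r, spacing * r, 0, up = -1))
  for (r in seq_len(len_b)) {
    hit <- which(contacts$res_b == r)
    if (length(hit) == 1L) {
      cb_x <- spacing * contacts$res_a[hit]
      cb_y <- contacts$distance[hit]
    } else {
      cb_x <- spacing * r
      cb_y <- separation
    }
    rows[[length(rows) + 1L]] <- residue("B", r, cb_x, cb_y, up = 1)
  }
  structure_model(do.call(rbind, rows))
}
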