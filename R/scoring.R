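#' Scalar coupling strength of one coupling matrix
#'
#' Reduces a 21 x 21 coupling matrix to the root-mean-square of its
#' entries. By default only the 20 x 20 amino-acid block enters (couplings
#' to the gap state largely reflect alignment artifacts); set
#' `include_gap = TRUE` to average over all 441 entries.
#'
#' @param w_ij A 21 x 21 numeric matrix.
#' @param include_gap Include the gap row/column in the average.
#' @return Non-negative scalar.
#' @export
coupling_strength <- function(w_ij, include_gap = FALSE) {
  stopifnot(is.matrix(w_ij), all(is.finite(w_ij)))
  blk <- if (include_gap) w_ij else w_ij[1:20, 1:20, drop = FALSE]
  sqrt(mean(blk^2))
}

#' Matrix of raw coupling strengths for a fit
#'
#' @param fit A [fit_plm] result.
#' @param include_gap Passed to [coupling_strength].
#' @return Symmetric L x L matrix with zero diagonal.
#' @export
strength_matrix <- function(fit, include_gap = FALSE) {
  L <- fit$L
  rows <- if (include_gap) 1:21 else 1:20
  s <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      s[i, j] <- sqrt(mean(fit$w[rows, rows, i, j]^2))
      s[j, i] <- s[i, j]
    }
  }
  s
}

#' Block-restricted average product correction
#'
#' Subtracts `<s_ik>_k * <s_kj>_k / <s_kl>_kl` from each strength, with the
#' averaging index sets restricted by protein: for an intra-A (intra-B) pair
#' all averages run over A (B) positions; for an inter pair the average over
#' `k` paired with `i` runs over B, the average paired with `j` over A, and
#' the denominator over the full inter block. This removes per-family
#' evolutionary-rate and entropy background while letting the two families
#' differ in rate.
#'
#' @param s Symmetric L x L strength matrix with zero diagonal.
#' @param boundary Last column of protein A.
#' @return Corrected matrix of the same shape (values may be negative).
#' @export
block_apc <- function(s, boundary) {
  L <- ncol(s)
  if (!isTRUE(all.equal(s, t(s)))) stop("strength matrix must be symmetric")
  if (any(diag(s) != 0)) stop("strength matrix must have zero diagonal")
  p <- boundary
  if (p < 1L || p >= L) stop("boundary out of range")
  ia <- seq_len(p)
  ib <- (p + 1L):L
  out <- matrix(0, L, L)

  correct_block <- function(block) {
    gm <- mean(block)
    if (gm == 0) stop("degenerate strength block (zero mean)")
    rm <- rowMeans(block)
    cm <- colMeans(block)
    block - outer(rm, cm) / gm
  }
  out[ia, ia] <- correct_block(s[ia, ia, drop = FALSE])
  out[ib, ib] <- correct_block(s[ib, ib, drop = FALSE])
  inter <- correct_block(s[ia, ib, drop = FALSE])
  out[ia, ib] <- inter
  out[ib, ia] <- t(inter)
  diag(out) <- 0
  out
}

#' Normalized coupling strength
#'
#' Divides corrected strengths by the mean of the `top_k` largest corrected
#' values over all unordered pairs (intra and inter); with the default
#' `top_k = round(3 L / 2)` a value above 1 marks stronger-than-typical
#' coupling, since a protein of length L has roughly 3L/2 contacts.
#'
#' @param s_corr Corrected strength matrix from [block_apc].
#' @param top_k Number of top values defining the normalizer.
#' @return List with `ncs` (normalized matrix) and `normalizer`.
#' @export
normalize_ncs <- function(s_corr, top_k = NULL) {
  L <- ncol(s_corr)
  vals <- s_corr[upper.tri(s_corr)]
  if (is.null(top_k)) top_k <- round(3 * L / 2)
  if (top_k < 1L || top_k > length(vals))
    stop("top_k must be between 1 and the number of pairs")
  normalizer <- mean(sort(vals, decreasing = TRUE)[seq_len(top_k)])
  if (normalizer <= 0) stop("nonpositive normalizer: no coupling signal")
  list(ncs = s_corr / normalizer, normalizer = normalizer)
}

#' Calibration constants for the contact-probability sigmoid
#'
#' Constants of the sigmoid mapping normalized coupling strength and
#' alignment depth to an empirical contact probability, fitted on the
#' bacterial 50S ribosomal subunit by the method's authors.
#'
#' @param m,c,sigma Sigmoid constants (defaults 0.47, 0.96, 9.77).
#' @return List of class `score_calibration`.
#' @export
score_calibration <- function(m = 0.47, c = 0.96, sigma = 9.77) {
  stopifnot(sigma > 0)
  structure(list(m = m, c = c, sigma = sigma), class = "score_calibration")
}

#' Calibrated contact score from normalized coupling strength
#'
#' `score = 1 / (1 + exp(-sigma * (x - mu)))` with
#' `mu = m / (N/L + 1) + c`: deeper alignments (larger N/L) lower the
#' midpoint toward `c`, so a given coupling strength is more trustworthy
#' when more sequences support it. For the complex's top-ranked pair
#' `x = sqrt(ncs)`; for every other pair `x = sqrt(ncs)` scaled by the
#' score of the top pair (pass it as `top_score`). Negative `ncs` values
#' are floored at zero before the square root.
#'
#' @param ncs Normalized coupling strength(s).
#' @param N Number of sequences in the paired alignment.
#' @param L Total number of positions (p + q).
#' @param top_score Score of the complex's top-ranked pair, or `NULL` when
#'   scoring that pair itself.
#' @param cal A [score_calibration].
#' @param mu_form `"ratio"` for `mu = m/(N/L + 1) + c` (default) or
#'   `"linear"` for `mu = m * (N/L + 1) + c`.
#' @return Score(s) in (0, 1).
#' @export
gremlin_score <- function(ncs, N, L, top_score = NULL,
                          cal = score_calibration(),
                          mu_form = c("ratio", "linear")) {
  mu_form <- match.arg(mu_form)
  stopifnot(N > 0, L > 0)
  r <- N / L
  mu <- if (mu_form == "ratio") cal$m / (r + 1) + cal$c
        else cal$m * (r + 1) + cal$c
  x <- sqrt(pmax(ncs, 0))
  if (!is.null(top_score)) x <- x * top_score
  1 / (1 + exp(-cal$sigma * (x - mu)))
}

#' Per-pair coupling scores for a fitted model
#'
#' Assembles, for every unordered position pair, the raw strength,
#' block-APC-corrected strength, normalized coupling strength and the
#' calibrated contact score, flagged as intra-A / intra-B / inter. The
#' complex's top pair (largest ncs over all pairs) is scored directly; all
#' other pairs are scaled by its score.
#'
#' @param fit A [fit_plm] result with a paired-alignment boundary.
#' @param include_gap Passed to [coupling_strength].
#' @param use_neff Use the effective (reweighted) sequence count rather
#'   than the raw row count as `N` in the depth ratio `N/L`.
#' @param cal A [score_calibration].
#' @param mu_form Passed to [gremlin_score].
#' @return A data frame of class `coupling_scores` with columns `i`, `j`,
#'   `resno_i`, `resno_j`, `chain_i`, `chain_j`, `s`, `s_corr`, `ncs`,
#'   `score`, `inter`, and attributes `boundary`, `N`, `L`, `normalizer`.
#' @export
coupling_scores <- function(fit, include_gap = FALSE, use_neff = FALSE,
                            cal = score_calibration(),
                            mu_form = c("ratio", "linear")) {
  mu_form <- match.arg(mu_form)
  if (is.na(fit$boundary))
    stop("fit has no boundary; coupling scores need a paired alignment")
  p <- fit$boundary
  L <- fit$L
  s <- strength_matrix(fit, include_gap)
  sc <- block_apc(s, p)
  nn <- normalize_ncs(sc)
  N <- if (use_neff) fit$neff else fit$N

  ut <- which(upper.tri(s), arr.ind = TRUE)
  i <- ut[, 1L]
  j <- ut[, 2L]
  ncs <- nn$ncs[ut]
  top <- which.max(ncs)
  top_score <- gremlin_score(ncs[top], N, L, NULL, cal, mu_form)
  score <- gremlin_score(ncs, N, L, top_score, cal, mu_form)
  score[top] <- top_score

  cma <- if (is.null(fit$colmap_a)) seq_len(p) else fit$colmap_a
  cmb <- if (is.null(fit$colmap_b)) seq_len(L - p) else fit$colmap_b
  resno <- function(k) ifelse(k <= p, cma[pmin(k, p)], cmb[pmax(k - p, 1L)])
  chain <- function(k) ifelse(k <= p, "A", "B")

  out <- data.frame(i = i, j = j,
                    resno_i = resno(i), resno_j = resno(j),
                    chain_i = chain(i), chain_j = chain(j),
                    s = s[ut], s_corr = sc[ut], ncs = ncs, score = score,
                    inter = i <= p & j > p,
                    stringsAsFactors = FALSE)
  attr(out, "boundary") <- p
  attr(out, "N") <- N
  attr(out, "L") <- L
  attr(out, "normalizer") <- nn$normalizer
  class(out) <- c("coupling_scores", "data.frame")
  out
}

#' Summed inter-protein coupling strength
#'
#' Sums the normalized coupling strengths of inter-protein pairs at or
#' above `threshold` — an interaction-evidence statistic for the protein
#' pair (0 when no pair reaches the threshold).
#'
#' @param scores A [coupling_scores] table.
#' @param threshold Minimum normalized coupling strength.
#' @return Non-negative scalar.
#' @export
summed_pair_coupling <- function(scores, threshold = 1.5) {
  v <- scores$ncs[scores$inter & scores$ncs >= threshold]
  if (length(v) == 0L) return(0)
  sum(v)
}

#' Rank scored pairs
#'
#' Orders pairs by decreasing calibrated score, ties broken by `(i, j)`
#' lexicographic order.
#'
#' @param scores A [coupling_scores] table.
#' @param which Restrict to `"inter"`, `"intra"`, or take `"all"` pairs.
#' @param top_n Keep at most this many pairs.
#' @return The reordered (sub)table.
#' @export
rank_pairs <- function(scores, which = c("inter", "intra", "all"),
                       top_n = Inf) {
  which <- match.arg(which)
  keep <- switch(which, inter = scores$inter, intra = !scores$inter,
                 all = rep(TRUE, nrow(scores)))
  out <- scores[keep, , drop = FALSE]
  out <- out[order(-out$score, out$i, out$j), , drop = FALSE]
  utils::head(out, top_n)
}

#' Write a score table as TSV
#'
#' @param scores A [coupling_scores] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.coupling_scores <- function(x, n = 10L, ...) {
  if (is.null(attr(x, "N")) || is.null(x$inter)) {
    # subsetting dropped the score-table metadata; print as plain data
    print(as.data.frame(x))
    return(invisible(x))
  }
  cat(sprintf(
    "Coupling scores: %d pairs (%d inter), N = %g, L = %d, boundary p = %d\n",
    nrow(x), sum(x$inter), attr(x, "N"), attr(x, "L"), attr(x, "boundary")))
  cat("Top pairs by calibrated score:\n")
  print(utils::head(as.data.frame(rank_pairs(x, "all")), n),
        row.names = FALSE)
  invisible(x)
}
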