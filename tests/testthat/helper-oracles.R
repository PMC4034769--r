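# Independent reference implementations used as oracles. These are written
# naively (explicit loops, direct formulas) and share no code with the
# package internals they check.

# naive negative pseudo-log-likelihood: v is L x 21, w a 21 x 21 x L x L
# array (symmetric, zero diagonal blocks), X an integer matrix of states
naive_npll <- function(v, w, X, wts, lambda_v, lambda_w) {
  N <- nrow(X)
  L <- ncol(X)
  A <- 21L
  total <- 0
  for (n in seq_len(N)) {
    for (i in seq_len(L)) {
      logits <- numeric(A)
      for (a in seq_len(A)) {
        z <- v[i, a]
        for (j in seq_len(L)) {
          if (j != i) z <- z + w[a, X[n, j], i, j]
        }
        logits[a] <- z
      }
      lse <- log(sum(exp(logits - max(logits)))) + max(logits)
      total <- total - wts[n] * (logits[X[n, i]] - lse)
    }
  }
  reg_w <- 0
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) reg_w <- reg_w + sum(w[, , i, j]^2)
  }
  total + lambda_v * sum(v^2) + lambda_w * reg_w
}

# brute-force all-pairs fractional identity (matches over columns where
# neither row is a gap, divided by the number of such columns)
naive_identity <- function(seqs, r, s) {
  both <- seqs[r, ] != "-" & seqs[s, ] != "-"
  if (!any(both)) return(0)
  mean(seqs[r, both] == seqs[s, both])
}

naive_weights <- function(seqs, thr) {
  n <- nrow(seqs)
  counts <- integer(n)
  for (r in seq_len(n)) {
    for (s in seq_len(n)) {
      if (naive_identity(seqs, r, s) >= thr) counts[r] <- counts[r] + 1L
    }
  }
  1 / counts
}

# empirical mutual information of two alignment columns
column_mi <- function(seqs, i, j) {
  tab <- table(seqs[, i], seqs[, j])
  p <- tab / sum(tab)
  pi <- rowSums(p)
  pj <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pi, pj)[nz]))
}

# random alignment with controllable gap content
random_msa <- function(n, L, gap_frac = 0, seed = NULL, query = NA_integer_) {
  if (!is.null(seed)) set.seed(seed)
  letters21 <- msa_alphabet[1:20]
  seqs <- matrix(sample(letters21, n * L, replace = TRUE), nrow = n)
  if (gap_frac > 0) {
    mask <- matrix(runif(n * L) < gap_frac, nrow = n)
    if (!is.na(query)) mask[query, ] <- FALSE
    seqs[mask] <- "-"
  }
  msa(seqs, sprintf("seq%03d", seq_len(n)), query = query)
}

# independent superposition oracle built on bio3d
bio3d_superpose_rmsd <- function(fixed, mobile) {
  moved <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(fixed)),
                                           mobile = as.vector(t(mobile))))
  sqrt(mean(rowSums((matrix(moved, ncol = 3, byrow = TRUE) - fixed)^2)))
}

# rigid motion of a structure_model: rotate then translate all atoms
rigid_move <- function(s, angles = c(0.4, -0.7, 1.1), shift = c(5, -3, 8)) {
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  R <- rz(angles[3]) %*% ry(angles[2]) %*% rx(angles[1])
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# minimal coupling_scores table for writer/restraint tests
fake_scores <- function(df, boundary, N, L) {
  attr(df, "boundary") <- boundary
  attr(df, "N") <- N
  attr(df, "L") <- L
  class(df) <- c("coupling_scores", "data.frame")
  df
}
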