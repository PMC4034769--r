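# Parameter packing shared with the compiled objective:
#   theta = [v by position (each a 21-block), couplings for pairs i<j in
#   row-major pair order, each block row-major over (state_i, state_j)].

n_theta <- function(L, A = 21L) L * A + (L * (L - 1L) / 2L) * A * A

pack_theta <- function(v, w, L, A = 21L) {
  th <- numeric(n_theta(L, A))
  th[seq_len(L * A)] <- as.vector(t(v))
  off <- L * A
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      th[off + seq_len(A * A)] <- as.vector(t(w[, , i, j]))
      off <- off + A * A
    }
  }
  th
}

unpack_theta <- function(theta, L, A = 21L) {
  v <- matrix(theta[seq_len(L * A)], nrow = L, ncol = A, byrow = TRUE)
  colnames(v) <- msa_alphabet[seq_len(A)]
  w <- array(0, dim = c(A, A, L, L))
  off <- L * A
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- matrix(theta[off + seq_len(A * A)], A, A, byrow = TRUE)
      w[, , i, j] <- blk
      w[, , j, i] <- t(blk)
      off <- off + A * A
    }
  }
  list(v = v, w = w)
}

model_theta <- function(model, L, A = 21L) {
  if (inherits(model, "potts_fit")) return(model$theta)
  pack_theta(model$v, model$w, L, A)
}

resolve_weights <- function(paln, weights, use_weights) {
  n <- nrow(paln$seqs)
  if (!is.null(weights)) {
    w <- as.numeric(weights)
    if (length(w) != n) stop("weights must have one entry per sequence")
    return(w)
  }
  if (use_weights) as.numeric(sequence_weights(paln)) else rep(1, n)
}

#' Negative regularized pseudo-log-likelihood of a Potts model
#'
#' The model assigns each paired sequence the global probability
#' `p(x) = exp(sum_i v_i(x_i) + sum_{i<j} w_ij(x_i, x_j)) / Z`. The
#' pseudo-likelihood replaces `p(x)` by the product over positions of the
#' conditional `P(x_i | x_{-i})`, each normalized over the 21 states, which
#' never requires the global partition function. This returns
#' `-sum_n wt_n sum_i log P(x_i^n | x_{-i}^n) + lambda_v ||v||^2 +
#' lambda_w ||w||^2`, couplings counted once per unordered pair.
#'
#' @param model A [fit_plm] result, or a list with elements `v` (L x 21
#'   matrix) and `w` (21 x 21 x L x L array, symmetric with zero diagonal
#'   blocks).
#' @param paln A [as_paired_msa()] (or any [msa]) the model dimensions match.
#' @param weights Optional per-sequence weights; default all 1.
#' @param lambda_v,lambda_w Ridge penalties on fields and couplings.
#' @return The scalar objective value.
#' @export
neg_pseudo_loglikelihood <- function(model, paln, weights = NULL,
                                     lambda_v = 0.01, lambda_w = 0.01) {
  X <- encode_msa(paln)
  L <- ncol(X)
  th <- model_theta(model, L)
  w <- resolve_weights(paln, weights, use_weights = FALSE)
  if (!is.null(weights)) w <- as.numeric(weights)
  plm_obj_grad(th, X, w, 21L, lambda_v, lambda_w, FALSE)$objective
}

#' Analytic gradient of the negative pseudo-log-likelihood
#'
#' Exact gradient of [neg_pseudo_loglikelihood] in the symmetric-coupling
#' parameterization (each unordered position pair counted once; the
#' returned array carries the pair gradient at `[, , i, j]` and its
#' transpose at `[, , j, i]`).
#'
#' @inheritParams neg_pseudo_loglikelihood
#' @return List with `v` (L x 21 matrix) and `w` (21 x 21 x L x L array).
#' @export
npll_gradient <- function(model, paln, weights = NULL, lambda_v = 0.01,
                          lambda_w = 0.01) {
  X <- encode_msa(paln)
  L <- ncol(X)
  th <- model_theta(model, L)
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  res <- plm_obj_grad(th, X, w, 21L, lambda_v, lambda_w, TRUE)
  g <- unpack_theta(res$gradient, L)
  # unpack mirrors pairs by transposition, which is what we want here
  g
}

#' Fit a Potts model by regularized pseudo-likelihood maximization
#'
#' Fits position-specific fields `v` and symmetric pairwise couplings `w`
#' of a 21-state Potts model (20 amino acids + gap) to a paired alignment
#' by minimizing the weighted negative pseudo-log-likelihood with ridge
#' penalties, using L-BFGS-B from zero initialization. The objective is
#' smooth and convex, so the optimum is unique for positive penalties and
#' independent of the starting point.
#'
#' @param paln A [as_paired_msa()] (a plain [msa] is accepted for
#'   single-protein fits; the boundary is then `NA`).
#' @param weights Optional per-sequence weights. When `NULL` they are
#'   computed by [sequence_weights] at 80% identity if `use_weights` is
#'   `TRUE`, otherwise set to 1.
#' @param lambda_v Ridge penalty on fields (default 0.01).
#' @param lambda_w Ridge penalty on couplings; default `0.01 * (L - 1)`
#'   where `L` is the number of columns, so the per-pair shrinkage grows
#'   with the number of competing pairs.
#' @param max_iter Maximum L-BFGS-B iterations.
#' @param tol Projected-gradient tolerance (`pgtol`).
#' @param factr Relative-objective stopping factor for L-BFGS-B.
#' @param init Optional starting parameter vector (packed); default zero.
#' @return An object of class `potts_fit` with components `v`, `w`,
#'   `theta`, `boundary`, `N`, `neff`, `weights`, `lambda_v`, `lambda_w`,
#'   `objective`, `pseudo_loglik`, `converged`, `message`, `niter`.
#' @seealso [coupling_scores] to reduce the fit to per-pair contact scores.
#' @export
fit_plm <- function(paln, weights = NULL, lambda_v = 0.01, lambda_w = NULL,
                    use_weights = TRUE, max_iter = 500L, tol = 1e-5,
                    factr = 1e8, init = NULL) {
  X <- encode_msa(paln)
  N <- nrow(X)
  L <- ncol(X)
  if (N < 2L || L < 2L)
    stop("need at least 2 sequences and 2 columns to fit")
  if (is.null(lambda_w)) lambda_w <- 0.01 * (L - 1)
  wts <- resolve_weights(paln, weights, use_weights)

  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  evaluate <- function(th) {
    res <- plm_obj_grad(th, X, wts, 21L, lambda_v, lambda_w, TRUE)
    cache$theta <- th
    cache$obj <- res$objective
    cache$grad <- res$gradient
    res
  }
  fn <- function(th) {
    if (!is.null(cache$theta) && identical(th, cache$theta)) return(cache$obj)
    evaluate(th)$objective
  }
  gr <- function(th) {
    if (!is.null(cache$theta) && identical(th, cache$theta)) return(cache$grad)
    evaluate(th)$gradient
  }

  par0 <- if (is.null(init)) numeric(n_theta(L)) else init
  if (length(par0) != n_theta(L)) stop("init has the wrong length")
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = factr))
  converged <- opt$convergence == 0L
  if (!converged)
    warning("pseudo-likelihood optimization stopped before convergence: ",
            opt$message)

  pars <- unpack_theta(opt$par, L)
  reg <- lambda_v * sum(pars$v^2) +
    lambda_w * sum(opt$par[-seq_len(L * 21L)]^2)
  structure(list(
    v = pars$v, w = pars$w, theta = opt$par,
    boundary = if (inherits(paln, "paired_msa")) paln$boundary else NA_integer_,
    L = L, A = 21L, N = N, neff = sum(wts), weights = wts,
    lambda_v = lambda_v, lambda_w = lambda_w,
    objective = opt$value, pseudo_loglik = -(opt$value - reg),
    converged = converged, message = opt$message,
    niter = opt$counts[["function"]],
    colmap_a = paln$colmap_a, colmap_b = paln$colmap_b,
    colmap = paln$colmap, call = match.call()),
    class = "potts_fit")
}

#' Extract one coupling matrix from a fit
#'
#' @param fit A [fit_plm] result.
#' @param i,j Positions (1-based, over the concatenated alignment).
#' @return The 21 x 21 coupling matrix `w_ij` (zero matrix when `i == j`).
#' @export
coupling_matrix <- function(fit, i, j) {
  m <- fit$w[, , i, j]
  dimnames(m) <- list(msa_alphabet, msa_alphabet)
  m
}

#' @export
print.potts_fit <- function(x, ...) {
  cat(sprintf("Potts model fit (pseudo-likelihood, L-BFGS-B)\n"))
  if (!is.na(x$boundary))
    cat(sprintf("  positions: %d + %d (boundary p = %d)\n",
                x$boundary, x$L - x$boundary, x$boundary))
  else
    cat(sprintf("  positions: %d\n", x$L))
  cat(sprintf("  sequences: %d (Neff = %.1f)\n", x$N, x$neff))
  cat(sprintf("  lambda_v = %g, lambda_w = %g\n", x$lambda_v, x$lambda_w))
  cat(sprintf("  objective = %.4f, %sconverged (%d evaluations)\n",
              x$objective, if (x$converged) "" else "NOT ", x$niter))
  invisible(x)
}

#' @export
coef.potts_fit <- function(object, ...) list(v = object$v, w = object$w)

#' @export
logLik.potts_fit <- function(object, ...) {
  structure(object$pseudo_loglik, df = length(object$theta),
            nobs = object$N, class = "logLik")
}

#' @export
summary.potts_fit <- function(object, n_top = 10L, ...) {
  s <- strength_matrix(object)
  ut <- which(upper.tri(s), arr.ind = TRUE)
  ord <- order(s[ut], decreasing = TRUE)[seq_len(min(n_top, nrow(ut)))]
  top <- data.frame(i = ut[ord, 1L], j = ut[ord, 2L],
                    strength = s[ut][ord])
  if (!is.na(object$boundary))
    top$inter <- top$i <= object$boundary & top$j > object$boundary
  out <- list(fit = object, top_pairs = top)
  class(out) <- "summary.potts_fit"
  out
}

#' @export
print.summary.potts_fit <- function(x, ...) {
  print(x$fit)
  cat("\nStrongest couplings (raw RMS strength):\n")
  print(x$top_pairs, row.names = FALSE)
  invisible(x)
}

#' @export
plot.potts_fit <- function(x, corrected = TRUE, ...) {
  s <- strength_matrix(x)
  if (corrected && !is.na(x$boundary)) s <- block_apc(s, x$boundary)
  graphics::image(seq_len(x$L), seq_len(x$L), s,
                  xlab = "position", ylab = "position",
                  main = if (corrected) "corrected coupling strength"
                         else "coupling strength", ...)
  if (!is.na(x$boundary)) {
    graphics::abline(h = x$boundary + 0.5, v = x$boundary + 0.5, lty = 2)
  }
  invisible(x)
}

#' Simulate sequences from a fitted Potts model
#'
#' Draws `nsim` sequences by single-chain Gibbs sampling from the fitted
#' global distribution (all 21 states, including the gap, can be emitted).
#'
#' @param object A [fit_plm] result.
#' @param nsim Number of sequences.
#' @param seed Optional seed passed to [set.seed].
#' @param burnin,thin Gibbs sweeps to discard and interval between kept
#'   sequences; defaults `100 * L` and 10.
#' @param ... Unused.
#' @return A [as_paired_msa()] (or [msa] for single-protein fits).
#' @export
simulate.potts_fit <- function(object, nsim = 1L, seed = NULL,
                               burnin = NULL, thin = 10L, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burnin)) burnin <- 100L * object$L
  L <- object$L
  A <- object$A
  Wflat <- expand_coupling_table(object$theta[-seq_len(L * A)], L, A)
  X <- gibbs_sample_potts(object$v, Wflat, L, A, A, as.integer(nsim),
                          as.integer(burnin), as.integer(thin))
  seqs <- matrix(msa_alphabet[X], nrow = nrow(X))
  aln <- msa(seqs, sprintf("sim%04d", seq_len(nrow(X))), query = NA_integer_)
  if (!is.na(object$boundary))
    aln <- as_paired_msa(aln, boundary = object$boundary,
                         genome_ids = aln$ids)
  aln
}

#' Per-sequence conditional log-probabilities under a fitted model
#'
#' @param object A [fit_plm] result.
#' @param newdata An alignment with the same number of columns.
#' @param type `"sequence"` for the summed pseudo-log-likelihood per row,
#'   `"position"` for the N x L matrix of `log P(x_i | x_-i)`.
#' @param ... Unused.
#' @return Numeric vector or matrix.
#' @export
predict.potts_fit <- function(object, newdata,
                              type = c("sequence", "position"), ...) {
  type <- match.arg(type)
  X <- encode_msa(newdata)
  if (ncol(X) != object$L)
    stop("newdata has a different number of columns than the fit")
  lp <- plm_cond_logprob(object$theta, X, object$A)
  if (type == "position") lp else rowSums(lp)
}

#' Serialize / restore a fitted Potts model
#'
#' The model is written as an RDS container next to a small JSON metadata
#' file (dimensions, penalties, sequence counts, boundary).
#'
#' @param fit A [fit_plm] result.
#' @param path Output `.rds` path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_potts <- function(fit, path) {
  saveRDS(fit, path)
  meta <- list(L = fit$L, A = fit$A, boundary = fit$boundary, N = fit$N,
               neff = fit$neff, lambda_v = fit$lambda_v,
               lambda_w = fit$lambda_w, objective = fit$objective,
               converged = fit$converged)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_potts
#' @export
load_potts <- function(path) readRDS(path)
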