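zero_model <- function(L) list(v = matrix(0, L, 21),
                               w = array(0, dim = c(21, 21, L, L)))

random_model <- function(L, seed, scale = 0.3) {
  set.seed(seed)
  v <- matrix(rnorm(L * 21, sd = scale), L, 21)
  w <- array(0, dim = c(21, 21, L, L))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      blk <- matrix(rnorm(441, sd = scale), 21, 21)
      w[, , i, j] <- blk
      w[, , j, i] <- t(blk)
    }
  }
  list(v = v, w = w)
}

small_paln <- function(n, L, seed) {
  set.seed(seed)
  seqs <- matrix(sample(msa_alphabet, n * L, replace = TRUE), nrow = n)
  as_paired_msa(msa(seqs, sprintf("s%03d", 1:n), query = NA_integer_),
                boundary = floor(L / 2),
                genome_ids = sprintf("g%03d", 1:n))
}

test_that("uniform conditionals give the closed-form objective", {
  paln <- small_paln(1, 10, seed = 21)
  val <- neg_pseudo_loglikelihood(zero_model(10), paln,
                                  weights = 1, lambda_v = 0, lambda_w = 0)
  expect_equal(val, 10 * log(21), tolerance = 1e-12)
})

test_that("the data term is linear in the sequence weights", {
  paln <- small_paln(6, 8, seed = 22)
  m <- random_model(8, seed = 23)
  reg <- neg_pseudo_loglikelihood(m, paln, weights = rep(0, 6),
                                  lambda_v = 0.01, lambda_w = 0.05)
  f1 <- neg_pseudo_loglikelihood(m, paln, weights = rep(1, 6),
                                 lambda_v = 0.01, lambda_w = 0.05)
  f2 <- neg_pseudo_loglikelihood(m, paln, weights = rep(2, 6),
                                 lambda_v = 0.01, lambda_w = 0.05)
  expect_equal(f2 - reg, 2 * (f1 - reg), tolerance = 1e-12)
})

test_that("objective matches the naive enumeration oracle", {
  paln <- small_paln(5, 6, seed = 24)
  m <- random_model(6, seed = 25)
  wts <- runif(5, 0.3, 1)
  got <- neg_pseudo_loglikelihood(m, paln, weights = wts, lambda_v = 0.013,
                                  lambda_w = 0.07)
  X <- matrix(match(paln$seqs, msa_alphabet), nrow = 5)
  want <- naive_npll(m$v, m$w, X, wts, 0.013, 0.07)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  paln <- small_paln(20, 12, seed = 26)
  m <- random_model(12, seed = 27, scale = 0.2)
  wts <- runif(20, 0.5, 1)
  g <- npll_gradient(m, paln, weights = wts, lambda_v = 0.01,
                     lambda_w = 0.05)
  h <- 1e-5

  fd_v <- function(i, a) {
    up <- m; up$v[i, a] <- up$v[i, a] + h
    dn <- m; dn$v[i, a] <- dn$v[i, a] - h
    (neg_pseudo_loglikelihood(up, paln, wts, 0.01, 0.05) -
       neg_pseudo_loglikelihood(dn, paln, wts, 0.01, 0.05)) / (2 * h)
  }
  fd_w <- function(a, b, i, j) {
    up <- m; up$w[a, b, i, j] <- up$w[a, b, i, j] + h
    up$w[b, a, j, i] <- up$w[b, a, j, i] + h
    dn <- m; dn$w[a, b, i, j] <- dn$w[a, b, i, j] - h
    dn$w[b, a, j, i] <- dn$w[b, a, j, i] - h
    (neg_pseudo_loglikelihood(up, paln, wts, 0.01, 0.05) -
       neg_pseudo_loglikelihood(dn, paln, wts, 0.01, 0.05)) / (2 * h)
  }

  set.seed(28)
  rel <- function(x, y) abs(x - y) / pmax(abs(y), 1e-2)
  errs <- c(
    vapply(1:40, function(k) {
      i <- sample(12, 1); a <- sample(21, 1)
      rel(g$v[i, a], fd_v(i, a))
    }, numeric(1)),
    vapply(1:60, function(k) {
      i <- sample(11, 1); j <- sample((i + 1):12, 1)
      a <- sample(21, 1); b <- sample(21, 1)
      rel(g$w[a, b, i, j], fd_w(a, b, i, j))
    }, numeric(1)))
  expect_lt(max(errs), 1e-5)
})

test_that("with zero data weight the gradient is the regularizer gradient", {
  paln <- small_paln(4, 5, seed = 29)
  m <- random_model(5, seed = 30)
  g <- npll_gradient(m, paln, weights = rep(0, 4), lambda_v = 0.02,
                     lambda_w = 0.3)
  expect_equal(g$v, 2 * 0.02 * m$v, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$w[, , 1, 3], 2 * 0.3 * m$w[, , 1, 3], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("identical sequences leave no usable coupling signal", {
  seqs <- matrix(rep(c("A", "C", "D", "E", "F", "G", "H", "I"), each = 30),
                 nrow = 30)
  paln <- as_paired_msa(msa(seqs, sprintf("s%02d", 1:30)), boundary = 4L,
                        genome_ids = sprintf("g%02d", 1:30))
  fit <- fit_plm(paln, use_weights = FALSE)
  # fields identify the observed letter at each position
  obs <- match(seqs[1, ], msa_alphabet)
  expect_equal(unname(apply(fit$v, 1, which.max)), obs)
  # without covariation the coupling strengths stay an order of magnitude
  # below the scale of a weak planted contact (~0.1 raw strength at
  # coupling 0.5); the conservation signal they do absorb is uniform
  # across pairs and removed by the average product correction
  s <- strength_matrix(fit, include_gap = TRUE)
  expect_lt(max(s), 0.1)
  corr <- block_apc(strength_matrix(fit), fit$boundary)
  expect_lt(max(abs(corr)), 0.02)
})

test_that("gradient norm is small at the optimum", {
  sim <- sample_potts(planted_complex_spec(p = 4, q = 4, n_contacts = 2,
                                           coupling = 1, n_seq = 150,
                                           seed = 31))
  fit <- fit_plm(sim$alignment, use_weights = FALSE, factr = 1e7)
  g <- npll_gradient(fit, sim$alignment, weights = fit$weights,
                     lambda_v = fit$lambda_v, lambda_w = fit$lambda_w)
  expect_lt(max(abs(g$v)), 0.05)
  expect_true(fit$converged)
  # optimum improves on the zero start
  obj0 <- neg_pseudo_loglikelihood(zero_model(8), sim$alignment,
                                   weights = fit$weights,
                                   lambda_v = fit$lambda_v,
                                   lambda_w = fit$lambda_w)
  expect_lt(fit$objective, obj0)
})

test_that("random restarts reach the same objective (convexity)", {
  sim <- sample_potts(planted_complex_spec(p = 4, q = 4, n_contacts = 2,
                                           coupling = 1, n_seq = 300,
                                           seed = 32))
  f0 <- fit_plm(sim$alignment, use_weights = FALSE)
  set.seed(33)
  init <- rnorm(length(f0$theta), sd = 0.05)
  f1 <- fit_plm(sim$alignment, use_weights = FALSE, init = init)
  expect_lt(abs(f0$objective - f1$objective) / abs(f0$objective), 1e-4)
})

test_that("doubling the coupling penalty never inflates coupling norms", {
  sim <- sample_potts(planted_complex_spec(p = 5, q = 5, n_contacts = 3,
                                           coupling = 1, n_seq = 300,
                                           seed = 34))
  f1 <- fit_plm(sim$alignment, use_weights = FALSE, lambda_w = 0.05)
  f2 <- fit_plm(sim$alignment, use_weights = FALSE, lambda_w = 0.10)
  s1 <- strength_matrix(f1, include_gap = TRUE)
  s2 <- strength_matrix(f2, include_gap = TRUE)
  expect_true(all(s2 <= s1 + 1e-6))
})

test_that("independent columns show no coupling above the permutation floor", {
  sim <- sample_potts(planted_complex_spec(p = 5, q = 5, n_contacts = 1,
                                           coupling = 0, n_seq = 400,
                                           seed = 35))
  fit <- fit_plm(sim$alignment, use_weights = FALSE)
  s_real <- strength_matrix(fit)
  # permuting rows within columns preserves marginals, destroys covariation
  set.seed(36)
  seqs <- apply(sim$alignment$seqs, 2, sample)
  perm <- as_paired_msa(msa(seqs, sim$alignment$ids), boundary = 5L,
                        genome_ids = sim$alignment$genome_ids)
  s_perm <- strength_matrix(fit_plm(perm, use_weights = FALSE))
  ut <- upper.tri(s_real)
  expect_lt(max(s_real[ut]), 2 * max(s_perm[ut]))
})

test_that("model methods are coherent and serialization round-trips", {
  sim <- sample_potts(planted_complex_spec(p = 4, q = 4, n_contacts = 2,
                                           coupling = 1.2, n_seq = 200,
                                           seed = 37))
  fit <- fit_plm(sim$alignment, use_weights = FALSE)
  expect_output(print(fit), "Potts model fit")
  expect_output(print(summary(fit)), "Strongest couplings")
  expect_equal(coef(fit)$v, fit$v)
  expect_equal(dim(coupling_matrix(fit, 1, 5)), c(21L, 21L))
  expect_equal(coupling_matrix(fit, 2, 6), t(coupling_matrix(fit, 6, 2)))
  expect_equal(as.numeric(logLik(fit)), fit$pseudo_loglik)

  lp <- predict(fit, sim$alignment, type = "position")
  expect_equal(dim(lp), c(200L, 8L))
  expect_true(all(lp <= 0))
  expect_equal(predict(fit, sim$alignment), rowSums(lp))

  gen <- simulate(fit, nsim = 25, seed = 38)
  expect_s3_class(gen, "paired_msa")
  expect_equal(dim(gen), c(25L, 8L))
  # simulated sequences score like training data, not like noise
  noise <- small_paln(25, 8, seed = 39)
  expect_gt(mean(predict(fit, gen)), mean(predict(fit, noise)))

  path <- tempfile(fileext = ".rds")
  save_potts(fit, path)
  back <- load_potts(path)
  expect_equal(back$theta, fit$theta)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$L, 8L)
})
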