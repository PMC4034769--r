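#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Parameter vector layout (shared with R side, see R/potts.R):
//   theta = [ v(0,0)..v(0,A-1), v(1,0).., ..., v(L-1,A-1),
//             w_k(a,b) for pairs k = (i<j) in row-major pair order,
//             each block row-major over (a,b) ]
// States in X are 1-based (1..A); A includes the gap state.

static inline std::size_t widx(int i, int j, int b, int a, int L, int A) {
  // contribution of state b at position j to the logit of state a at i
  return ((static_cast<std::size_t>(i) * L + j) * A + b) * A + a;
}

// Expand the packed symmetric couplings into a full L x L x A x A table so
// the per-sequence inner loop is a contiguous A-element add. The table is
// laid out i-major: the slab for one position i is contiguous (L*A*A
// doubles) and stays cache-resident while all sequences are processed.
static void expand_couplings(const double* th, int L, int A,
                             std::vector<double>& W) {
  std::fill(W.begin(), W.end(), 0.0);
  std::size_t off = static_cast<std::size_t>(L) * A;
  for (int i = 0; i < L - 1; ++i) {
    for (int j = i + 1; j < L; ++j) {
      for (int a = 0; a < A; ++a) {
        for (int b = 0; b < A; ++b) {
          double val = th[off + static_cast<std::size_t>(a) * A + b];
          W[widx(i, j, b, a, L, A)] = val;
          W[widx(j, i, a, b, L, A)] = val;
        }
      }
      off += static_cast<std::size_t>(A) * A;
    }
  }
}

// [[Rcpp::export]]
List plm_obj_grad(NumericVector theta, IntegerMatrix X, NumericVector wts,
                  int A, double lambda_v, double lambda_w, bool want_grad) {
  const int N = X.nrow(), L = X.ncol();
  const std::size_t nv = static_cast<std::size_t>(L) * A;
  const std::size_t npair = static_cast<std::size_t>(L) * (L - 1) / 2;
  const std::size_t ntheta = nv + npair * A * A;
  if (static_cast<std::size_t>(theta.size()) != ntheta)
    stop("parameter vector has length %d, expected %d",
         (int)theta.size(), (int)ntheta);
  if (wts.size() != N) stop("weights length must equal number of sequences");

  const double* th = REAL(theta);
  std::vector<double> W(static_cast<std::size_t>(L) * L * A * A);
  expand_couplings(th, L, A, W);

  // row-major copy of the alignment (one sequence contiguous)
  std::vector<int> Xrm(static_cast<std::size_t>(N) * L);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < L; ++j) {
      int s = X(n, j);
      if (s < 1 || s > A) stop("state out of range at row %d", n + 1);
      Xrm[static_cast<std::size_t>(n) * L + j] = s - 1;
    }

  std::vector<double> gW;
  NumericVector grad;
  double* gv = nullptr;
  if (want_grad) {
    grad = NumericVector(ntheta);
    gv = REAL(grad);
    gW.assign(W.size(), 0.0);
  }

  std::vector<double> acc(A), prob(A);
  double obj = 0.0;

  // position-outer loop: the W and gradient slabs for position i fit in
  // cache while all N sequences stream through
  for (int i = 0; i < L; ++i) {
    const double* vi = th + static_cast<std::size_t>(i) * A;
    const double* Wi = &W[static_cast<std::size_t>(i) * L * A * A];
    double* gWi = want_grad ? &gW[static_cast<std::size_t>(i) * L * A * A]
                            : nullptr;
    double* gvi = want_grad ? gv + static_cast<std::size_t>(i) * A : nullptr;
    for (int n = 0; n < N; ++n) {
      const double wt = wts[n];
      const int* xrow = &Xrm[static_cast<std::size_t>(n) * L];
      for (int a = 0; a < A; ++a) acc[a] = vi[a];
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        const double* wp = Wi + (static_cast<std::size_t>(j) * A + xrow[j]) * A;
        for (int a = 0; a < A; ++a) acc[a] += wp[a];
      }
      double mx = acc[0];
      for (int a = 1; a < A; ++a) if (acc[a] > mx) mx = acc[a];
      double Z = 0.0;
      for (int a = 0; a < A; ++a) { prob[a] = std::exp(acc[a] - mx); Z += prob[a]; }
      obj -= wt * (acc[xrow[i]] - (mx + std::log(Z)));
      if (want_grad) {
        const double invZ = wt / Z;
        for (int a = 0; a < A; ++a) prob[a] *= invZ;
        prob[xrow[i]] -= wt;
        for (int a = 0; a < A; ++a) gvi[a] += prob[a];
        for (int j = 0; j < L; ++j) {
          if (j == i) continue;
          double* gp = gWi + (static_cast<std::size_t>(j) * A + xrow[j]) * A;
          for (int a = 0; a < A; ++a) gp[a] += prob[a];
        }
      }
    }
  }

  // regularization: lambda_v ||v||^2 + lambda_w ||w||^2 (each pair once)
  double reg = 0.0;
  for (std::size_t t = 0; t < nv; ++t) reg += lambda_v * th[t] * th[t];
  for (std::size_t t = nv; t < ntheta; ++t) reg += lambda_w * th[t] * th[t];
  obj += reg;

  if (want_grad) {
    // collapse the full-table gradient back onto the packed pairs
    std::size_t off = nv;
    for (int i = 0; i < L - 1; ++i) {
      for (int j = i + 1; j < L; ++j) {
        for (int a = 0; a < A; ++a)
          for (int b = 0; b < A; ++b)
            gv[off + static_cast<std::size_t>(a) * A + b] =
              gW[widx(i, j, b, a, L, A)] + gW[widx(j, i, a, b, L, A)];
        off += static_cast<std::size_t>(A) * A;
      }
    }
    for (std::size_t t = 0; t < nv; ++t) gv[t] += 2.0 * lambda_v * th[t];
    for (std::size_t t = nv; t < ntheta; ++t) gv[t] += 2.0 * lambda_w * th[t];
    return List::create(_["objective"] = obj, _["gradient"] = grad);
  }
  return List::create(_["objective"] = obj);
}

// Per-position conditional log-probabilities log P(x_i | x_{-i}) for each
// sequence; used by predict().
// [[Rcpp::export]]
NumericMatrix plm_cond_logprob(NumericVector theta, IntegerMatrix X, int A) {
  const int N = X.nrow(), L = X.ncol();
  const double* th = REAL(theta);
  std::vector<double> W(static_cast<std::size_t>(L) * L * A * A);
  expand_couplings(th, L, A, W);
  NumericMatrix out(N, L);
  std::vector<int> xrow(L);
  std::vector<double> acc(A);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < L; ++j) xrow[j] = X(n, j) - 1;
    for (int i = 0; i < L; ++i) {
      const double* vi = th + static_cast<std::size_t>(i) * A;
      for (int a = 0; a < A; ++a) acc[a] = vi[a];
      for (int j = 0; j < L; ++j) {
        if (j == i) continue;
        const double* wp = &W[widx(i, j, xrow[j], 0, L, A)];
        for (int a = 0; a < A; ++a) acc[a] += wp[a];
      }
      double mx = acc[0];
      for (int a = 1; a < A; ++a) if (acc[a] > mx) mx = acc[a];
      double Z = 0.0;
      for (int a = 0; a < A; ++a) Z += std::exp(acc[a] - mx);
      out(n, i) = acc[xrow[i]] - (mx + std::log(Z));
    }
  }
  return out;
}

// Single-chain Gibbs sampler over sequences of length L with A total states
// of which the first n_active can be emitted (lets callers exclude the gap
// state). Uses R's RNG so set.seed() governs reproducibility. Position
// pairs whose coupling block is identically zero are skipped, so sampling
// from sparse planted models costs O(nonzero pairs) per sweep.
// v: L x A fields; Wflat: expanded coupling table in widx() layout.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_potts(NumericMatrix v, NumericVector Wflat, int L,
                                 int A, int n_active, int n_seq, int burnin,
                                 int thin) {
  if (v.nrow() != L || v.ncol() != A) stop("field matrix must be L x A");
  if (static_cast<std::size_t>(Wflat.size()) !=
      static_cast<std::size_t>(L) * L * A * A)
    stop("coupling table has wrong size");
  const double* W = REAL(Wflat);

  // neighbor lists: j is a neighbor of i iff block (i,j) is not all zero
  std::vector<std::vector<int> > nbr(L);
  const std::size_t blk = static_cast<std::size_t>(A) * A;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      if (j == i) continue;
      const double* base = W + ((static_cast<std::size_t>(i) * L + j) * blk);
      bool nz = false;
      for (std::size_t t = 0; t < blk; ++t)
        if (base[t] != 0.0) { nz = true; break; }
      if (nz) nbr[i].push_back(j);
    }
  }

  std::vector<int> x(L);
  for (int i = 0; i < L; ++i)
    x[i] = static_cast<int>(unif_rand() * n_active);
  IntegerMatrix out(n_seq, L);
  std::vector<double> acc(n_active), p(n_active);
  const long total = static_cast<long>(burnin) +
                     static_cast<long>(thin) * n_seq;
  int kept = 0;
  for (long sweep = 1; sweep <= total && kept < n_seq; ++sweep) {
    for (int i = 0; i < L; ++i) {
      for (int a = 0; a < n_active; ++a) acc[a] = v(i, a);
      for (std::size_t t = 0; t < nbr[i].size(); ++t) {
        int j = nbr[i][t];
        const double* wp = &W[widx(i, j, x[j], 0, L, A)];
        for (int a = 0; a < n_active; ++a) acc[a] += wp[a];
      }
      double mx = acc[0];
      for (int a = 1; a < n_active; ++a) if (acc[a] > mx) mx = acc[a];
      double Z = 0.0;
      for (int a = 0; a < n_active; ++a) { p[a] = std::exp(acc[a] - mx); Z += p[a]; }
      double u = unif_rand() * Z, cum = 0.0;
      int pick = n_active - 1;
      for (int a = 0; a < n_active; ++a) {
        cum += p[a];
        if (u <= cum) { pick = a; break; }
      }
      x[i] = pick;
    }
    if (sweep > burnin && (sweep - burnin) % thin == 0) {
      for (int i = 0; i < L; ++i) out(kept, i) = x[i] + 1;
      ++kept;
    }
  }
  return out;
}

// Helper for the sampler: expand packed pair couplings (same layout as the
// tail of theta in plm_obj_grad) into the full table.
// [[Rcpp::export]]
NumericVector expand_coupling_table(NumericVector wpacked, int L, int A) {
  const std::size_t npair = static_cast<std::size_t>(L) * (L - 1) / 2;
  if (static_cast<std::size_t>(wpacked.size()) != npair * A * A)
    stop("packed coupling vector has wrong length");
  std::vector<double> th(static_cast<std::size_t>(L) * A + npair * A * A, 0.0);
  std::copy(wpacked.begin(), wpacked.end(),
            th.begin() + static_cast<std::size_t>(L) * A);
  std::vector<double> W(static_cast<std::size_t>(L) * L * A * A);
  expand_couplings(th.data(), L, A, W);
  return NumericVector(W.begin(), W.end());
}
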