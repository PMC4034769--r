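#include <Rcpp.h>
using namespace Rcpp;

// Fractional identity between rows r and s: matches over columns where
// neither row is the gap state, divided by the number of such columns
// (0 when no shared non-gap columns).
static double row_identity(const int* X, int N, int L, int r, int s,
                           int gap) {
  int match = 0, denom = 0;
  for (int c = 0; c < L; ++c) {
    int a = X[static_cast<std::size_t>(c) * N + r];
    int b = X[static_cast<std::size_t>(c) * N + s];
    if (a == gap || b == gap) continue;
    ++denom;
    if (a == b) ++match;
  }
  return denom == 0 ? 0.0 : static_cast<double>(match) / denom;
}

// Sequence reweighting: weight of row r is 1 / (# rows with identity >= thr
// to r, including itself).
// [[Rcpp::export]]
NumericVector seq_weights_cpp(IntegerMatrix X, int gap, double thr) {
  const int N = X.nrow(), L = X.ncol();
  const int* xp = INTEGER(X);
  std::vector<int> counts(N, 1);
  for (int r = 0; r < N - 1; ++r) {
    for (int s = r + 1; s < N; ++s) {
      if (row_identity(xp, N, L, r, s, gap) >= thr) {
        ++counts[r];
        ++counts[s];
      }
    }
  }
  NumericVector w(N);
  for (int r = 0; r < N; ++r) w[r] = 1.0 / counts[r];
  return w;
}

// Greedy redundancy filter: scan rows in the given order (0-based), keep a
// row iff its identity to every previously kept row is <= max_id.
// [[Rcpp::export]]
LogicalVector greedy_redundancy_cpp(IntegerMatrix X, int gap, double max_id,
                                    IntegerVector scan_order) {
  const int N = X.nrow(), L = X.ncol();
  const int* xp = INTEGER(X);
  LogicalVector keep(N, false);
  std::vector<int> kept;
  kept.reserve(N);
  for (int k = 0; k < scan_order.size(); ++k) {
    int r = scan_order[k];
    bool ok = true;
    for (std::size_t t = 0; t < kept.size(); ++t) {
      if (row_identity(xp, N, L, r, kept[t], gap) > max_id) {
        ok = false;
        break;
      }
    }
    if (ok) {
      keep[r] = true;
      kept.push_back(r);
    }
  }
  return keep;
}

// All-pairs identity matrix (for summaries/diagnostics on small alignments).
// [[Rcpp::export]]
NumericMatrix pairwise_identity_cpp(IntegerMatrix X, int gap) {
  const int N = X.nrow(), L = X.ncol();
  const int* xp = INTEGER(X);
  NumericMatrix out(N, N);
  for (int r = 0; r < N; ++r) {
    out(r, r) = 1.0;
    for (int s = r + 1; s < N; ++s) {
      double id = row_identity(xp, N, L, r, s, gap);
      out(r, s) = id;
      out(s, r) = id;
    }
  }
  return out;
}
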