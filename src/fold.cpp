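#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// base encoding: 0=A 1=C 2=G 3=U
static inline double pair_weight(int a, int b, double w_gc, double w_au,
                                 double w_gu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return w_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return w_au;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return w_gu;
  return 0.0;
}

// Weighted Nussinov base-pair maximisation with a minimum hairpin loop and a
// maximum pairing span. Score is the summed (positive) pair weight of the
// optimal structure; the caller negates it into an energy proxy. Traceback
// yields a dot-bracket string.
// [[Rcpp::export(name = ".nussinov_fold_c")]]
List nussinov_fold_c(IntegerVector seq, int max_span, int min_loop,
                     double w_gc, double w_au, double w_gu) {
  const int n = seq.size();
  std::string db(n, '.');
  if (n < 2) {
    return List::create(_["score"] = 0.0, _["structure"] = db);
  }
  // S[i][j] stored as flat row-major upper triangle
  std::vector<double> S((size_t)n * n, 0.0);
  const double eps = 1e-9;
#define IDX(i, j) ((size_t)(i) * n + (j))
  for (int d = min_loop + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      double best = S[IDX(i, j - 1)];
      const int kmin = std::max(i, j - max_span);
      for (int k = kmin; k <= j - min_loop - 1; ++k) {
        const double w = pair_weight(seq[k], seq[j], w_gc, w_au, w_gu);
        if (w <= 0.0) continue;
        double v = w;
        if (k > i) v += S[IDX(i, k - 1)];
        if (k + 1 <= j - 1) v += S[IDX(k + 1, j - 1)];
        if (v > best) best = v;
      }
      S[IDX(i, j)] = best;
    }
  }
  // traceback (iterative; recompute the winning decomposition)
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first;
    const int j = stack.back().second;
    stack.pop_back();
    if (i >= j || S[IDX(i, j)] <= eps) continue;
    if (S[IDX(i, j)] <= S[IDX(i, j - 1)] + eps) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    const int kmin = std::max(i, j - max_span);
    for (int k = kmin; k <= j - min_loop - 1; ++k) {
      const double w = pair_weight(seq[k], seq[j], w_gc, w_au, w_gu);
      if (w <= 0.0) continue;
      double v = w;
      if (k > i) v += S[IDX(i, k - 1)];
      if (k + 1 <= j - 1) v += S[IDX(k + 1, j - 1)];
      if (v >= S[IDX(i, j)] - eps) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
#undef IDX
  return List::create(_["score"] = S[(size_t)0 * n + (n - 1)],
                      _["structure"] = db);
}
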