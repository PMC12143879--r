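#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Delayed transfer entropy on binary 1 ms trains with single-bin histories:
// TE(d) over the joint distribution of (y_t, y_{t-1}, x_{t-d}).
static double te_single(const int* x, const int* y, int n, int d) {
  double cnt[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int t0 = std::max(1, d);
  double tot = 0;
  for (int t = t0; t < n; ++t) {
    int yi = y[t] > 0, yj = y[t - 1] > 0, xk = x[t - d] > 0;
    cnt[(yi << 2) | (yj << 1) | xk] += 1.0;
    tot += 1.0;
  }
  if (tot <= 0) return 0.0;
  double te = 0.0;
  for (int yi = 0; yi < 2; ++yi) {
    for (int yj = 0; yj < 2; ++yj) {
      for (int xk = 0; xk < 2; ++xk) {
        double pijk = cnt[(yi << 2) | (yj << 1) | xk] / tot;
        if (pijk <= 0) continue;
        double pjk = (cnt[(0 << 2) | (yj << 1) | xk] +
                      cnt[(1 << 2) | (yj << 1) | xk]) / tot;
        double pj = (cnt[(0 << 2) | (yj << 1) | 0] + cnt[(0 << 2) | (yj << 1) | 1] +
                     cnt[(1 << 2) | (yj << 1) | 0] + cnt[(1 << 2) | (yj << 1) | 1]) / tot;
        double pij = (cnt[(yi << 2) | (yj << 1) | 0] +
                      cnt[(yi << 2) | (yj << 1) | 1]) / tot;
        // p(yi | yj, xk) / p(yi | yj)
        double num = pijk / pjk;
        double den = pij / pj;
        te += pijk * std::log2(num / den);
      }
    }
  }
  return te;
}

// [[Rcpp::export]]
NumericVector te_delay_scan_cpp(IntegerVector src, IntegerVector tgt, int dmax) {
  int n = src.size();
  if (tgt.size() != n) stop("length mismatch");
  NumericVector out(dmax + 1);
  for (int d = 0; d <= dmax; ++d) out[d] = te_single(src.begin(), tgt.begin(), n, d);
  return out;
}

// Max-over-delay TE for each circular shift of the source train.
// [[Rcpp::export]]
NumericVector te_perm_scan_cpp(IntegerVector src, IntegerVector tgt, int dmax,
                               IntegerVector shifts) {
  int n = src.size();
  std::vector<int> xs(n);
  NumericVector out(shifts.size());
  for (int s = 0; s < shifts.size(); ++s) {
    int k = shifts[s] % n;
    if (k < 0) k += n;
    for (int t = 0; t < n; ++t) xs[(t + k) % n] = src[t];
    double best = -1e300;
    for (int d = 0; d <= dmax; ++d) {
      double v = te_single(xs.data(), tgt.begin(), n, d);
      if (v > best) best = v;
    }
    out[s] = best;
  }
  return out;
}

// K nearest neighbors among delay-embedding points, excluding self and
// same-trial points within `excl` ms (Theiler window against trivial
// temporal neighbors); returns 1-based indices and exponential simplex
// weights.
// [[Rcpp::export]]
List knn_simplex_cpp(NumericMatrix emb, IntegerVector trial,
                     IntegerVector tvec, int K, int excl) {
  int P = emb.nrow(), E = emb.ncol();
  IntegerMatrix idx(P, K);
  NumericMatrix wt(P, K);
  std::vector<double> d2(P);
  std::vector<int> ord(P);
  for (int i = 0; i < P; ++i) {
    for (int j = 0; j < P; ++j) {
      if (j == i ||
          (trial[j] == trial[i] && std::abs(tvec[j] - tvec[i]) <= excl)) {
        d2[j] = R_PosInf;
        continue;
      }
      double s = 0;
      for (int e = 0; e < E; ++e) {
        double df = emb(i, e) - emb(j, e);
        s += df * df;
      }
      d2[j] = s;
    }
    std::iota(ord.begin(), ord.end(), 0);
    std::partial_sort(ord.begin(), ord.begin() + K, ord.end(),
                      [&](int a, int b) { return d2[a] < d2[b]; });
    double d1 = std::sqrt(d2[ord[0]]);
    double wsum = 0;
    for (int k = 0; k < K; ++k) {
      idx(i, k) = ord[k] + 1;
      double dk = std::sqrt(d2[ord[k]]);
      double w = (d1 > 0) ? std::exp(-dk / d1) : (dk == 0 ? 1.0 : 0.0);
      wt(i, k) = w;
      wsum += w;
    }
    if (wsum <= 0) wsum = 1;
    for (int k = 0; k < K; ++k) wt(i, k) /= wsum;
  }
  return List::create(_["idx"] = idx, _["w"] = wt);
}
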