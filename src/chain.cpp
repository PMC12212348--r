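#include "panmem.h"
using namespace Rcpp;

// Colinear chaining over anchors (x = read start, y = target start, l =
// length) on a single (haplotype, strand).  Chain score DP:
//   f(j) = max( l_j, max_i f(i) + min(dy, dx, l_j) - gap(|dy - dx|) )
// over predecessors with x_i < x_j, y_i < y_j and both dx, dy <= max_gap,
// where gap(d) = 0 if d == 0 else c1*d + c2*log2(d).  Chains are extracted
// best-first; anchors of an extracted chain are removed and the DP is rerun,
// which keeps chains disjoint (anchor counts per group are small).
ChainOut chain_anchors_impl(const std::vector<int>& x,
                                   const std::vector<int>& y,
                                   const std::vector<int>& l,
                                   double c1, double c2, int max_gap,
                                   double min_score, int max_chains) {
  ChainOut out;
  int k = (int)x.size();
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (y[a] != y[b]) return y[a] < y[b];
    return x[a] < x[b];
  });
  std::vector<char> used(k, 0);
  while ((int)out.chains.size() < max_chains) {
    std::vector<double> f(k, 0.0);
    std::vector<int> pred(k, -1);
    double best = -1.0;
    int best_j = -1;
    for (int jo = 0; jo < k; ++jo) {
      int j = ord[jo];
      if (used[j]) continue;
      f[j] = (double)l[j];
      for (int io = 0; io < jo; ++io) {
        int i = ord[io];
        if (used[i]) continue;
        int dx = x[j] - x[i], dy = y[j] - y[i];
        if (dx <= 0 || dy <= 0 || dx > max_gap || dy > max_gap) continue;
        double gain = (double)std::min(std::min(dx, dy), l[j]);
        int d = std::abs(dy - dx);
        double cost = d == 0 ? 0.0 : c1 * d + c2 * std::log2((double)d);
        double cand = f[i] + gain - cost;
        if (cand > f[j]) { f[j] = cand; pred[j] = i; }
      }
      if (f[j] > best) { best = f[j]; best_j = j; }
    }
    if (best_j < 0 || best < min_score) break;
    std::vector<int> chain;
    for (int j = best_j; j >= 0; j = pred[j]) { chain.push_back(j); used[j] = 1; }
    std::reverse(chain.begin(), chain.end());
    out.chains.push_back(chain);
    out.scores.push_back(best);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_chain_anchors(IntegerVector x, IntegerVector y, IntegerVector l,
                       double c1, double c2, int max_gap, double min_score,
                       int max_chains) {
  std::vector<int> xv(x.begin(), x.end()), yv(y.begin(), y.end()),
      lv(l.begin(), l.end());
  ChainOut co = chain_anchors_impl(xv, yv, lv, c1, c2, max_gap, min_score, max_chains);
  List chains(co.chains.size());
  for (size_t i = 0; i < co.chains.size(); ++i) {
    IntegerVector ch(co.chains[i].begin(), co.chains[i].end());
    chains[i] = ch + 1; // 1-based for R
  }
  return List::create(_["chains"] = chains,
                      _["scores"] = NumericVector(co.scores.begin(), co.scores.end()));
}
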