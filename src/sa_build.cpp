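#include "panmem.h"
using namespace Rcpp;

// Suffix array by prefix doubling.  O(n log^2 n): ranks are doubled log n
// times, each round re-sorting index pairs.  Straightforward and easy to
// verify; at desk scale (a few MB) this finishes in seconds.
static std::vector<int> suffix_array_doubling(const uint8_t* s, int n) {
  std::vector<int> sa(n), rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's LCP: LCP[i] = lcp(suffix at SA[i-1], suffix at SA[i]); LCP[0] = 0.
static std::vector<int> lcp_kasai(const uint8_t* s, int n, const std::vector<int>& sa) {
  std::vector<int> isa(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) isa[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (isa[i] > 0) {
      int j = sa[isa[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[isa[i]] = h;
      if (h > 0) --h;
    } else h = 0;
  }
  return lcp;
}

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(RawVector text) {
  int n = text.size();
  if (n == 0) stop("empty text");
  std::vector<int> sa = suffix_array_doubling(RAW(text), n);
  return IntegerVector(sa.begin(), sa.end());
}

// Build the run-length BWT index: runs, boundary SA samples, per-character
// run lists with cumulative counts, LCP-derived thresholds and the phi
// predecessor arrays.  The final byte acts as the terminator: it must occur
// exactly once and be strictly smaller than every other byte of the text.
// [[Rcpp::export]]
List cpp_build_rindex(RawVector text) {
  int n = text.size();
  if (n < 2) stop("text too short to index");
  const uint8_t* s = RAW(text);
  for (int i = 0; i < n - 1; ++i)
    if (s[i] <= s[n - 1])
      stop("the final byte must be a unique, strictly smallest terminator");

  std::vector<int> sa = suffix_array_doubling(s, n);
  std::vector<int> lcp = lcp_kasai(s, n, sa);

  std::vector<uint8_t> bwt(n);
  for (int i = 0; i < n; ++i) bwt[i] = sa[i] == 0 ? s[n - 1] : s[sa[i] - 1];

  // runs
  std::vector<int> run_start, run_len, sa_first, sa_last;
  std::vector<uint8_t> run_char;
  for (int i = 0; i < n;) {
    int j = i;
    while (j + 1 < n && bwt[j + 1] == bwt[i]) ++j;
    run_char.push_back(bwt[i]);
    run_start.push_back(i);
    run_len.push_back(j - i + 1);
    sa_first.push_back(sa[i]);
    sa_last.push_back(sa[j]);
    i = j + 1;
  }
  int r = (int)run_char.size();

  IntegerVector Ccum(257);
  {
    std::vector<int> cnt(256, 0);
    for (int i = 0; i < n; ++i) cnt[s[i]]++;
    int acc = 0;
    for (int b = 0; b < 256; ++b) { Ccum[b] = acc; acc += cnt[b]; }
    Ccum[256] = acc;
  }

  // per-character run lists, cumulative counts and thresholds
  IntegerVector cr_off(257);
  IntegerVector cr_runs(r), cr_cum(r), cr_thresh(r);
  {
    std::vector<int> nrun(256, 0);
    for (int k = 0; k < r; ++k) nrun[run_char[k]]++;
    int acc = 0;
    for (int b = 0; b < 256; ++b) { cr_off[b] = acc; acc += nrun[b]; }
    cr_off[256] = acc;
    std::vector<int> fill(256, 0), cum(256, 0), prev_end(256, -1);
    for (int k = 0; k < r; ++k) {
      uint8_t c = run_char[k];
      int slot = cr_off[c] + fill[c]++;
      cr_runs[slot] = k;
      cr_cum[slot] = cum[c];
      cum[c] += run_len[k];
      if (prev_end[c] < 0) {
        cr_thresh[slot] = 0;
      } else {
        // first position of the minimum LCP value in (prev_end, run_start]
        int best_row = prev_end[c] + 1, best = lcp[best_row];
        for (int row = prev_end[c] + 2; row <= run_start[k]; ++row)
          if (lcp[row] < best) { best = lcp[row]; best_row = row; }
        cr_thresh[slot] = best_row;
      }
      prev_end[c] = run_start[k] + run_len[k] - 1;
    }
  }

  // phi samples: key = SA at run start (rows >= 1), val = SA at previous row
  std::vector<std::pair<int,int>> ph;
  ph.reserve(r);
  for (int k = 1; k < r; ++k)
    ph.push_back(std::make_pair(sa[run_start[k]], sa[run_start[k] - 1]));
  std::sort(ph.begin(), ph.end());
  IntegerVector phi_key(ph.size()), phi_val(ph.size());
  for (size_t i = 0; i < ph.size(); ++i) {
    phi_key[i] = ph[i].first;
    phi_val[i] = ph[i].second;
  }

  return List::create(
      _["n"] = n, _["r"] = r, _["text"] = text,
      _["run_char"] = RawVector(run_char.begin(), run_char.end()),
      _["run_start"] = IntegerVector(run_start.begin(), run_start.end()),
      _["run_len"] = IntegerVector(run_len.begin(), run_len.end()),
      _["sa_first"] = IntegerVector(sa_first.begin(), sa_first.end()),
      _["sa_last"] = IntegerVector(sa_last.begin(), sa_last.end()),
      _["Ccum"] = Ccum, _["cr_off"] = cr_off, _["cr_runs"] = cr_runs,
      _["cr_cum"] = cr_cum, _["cr_thresh"] = cr_thresh,
      _["phi_key"] = phi_key, _["phi_val"] = phi_val);
}

// Explicit BWT, expanded from the runs (diagnostics/tests).
// [[Rcpp::export]]
RawVector cpp_bwt(List idx) {
  IndexView v(idx);
  RawVector out(v.n);
  int pos = 0;
  for (int k = 0; k < v.r; ++k)
    for (int i = 0; i < v.run_len[k]; ++i) out[pos++] = v.run_char[k];
  return out;
}
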