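#include "panmem.h"
using namespace Rcpp;

// Backward-search state: half-open row range [lo, hi) plus a toehold, the SA
// value of row hi-1.  Implemented over the run-length BWT only.

// [[Rcpp::export]]
IntegerVector cpp_init_range(List idx) {
  IndexView v(idx);
  // SA[n-1] is the last row of the last run
  return IntegerVector::create(0, v.n, v.sa_last[v.r - 1]);
}

static bool backward_step_impl(const IndexView& v, int lo, int hi, int toehold,
                               uint8_t c, int* nlo, int* nhi, int* ntoe) {
  int l2 = v.Ccum[c] + v.rank(c, lo);
  int h2 = v.Ccum[c] + v.rank(c, hi);
  if (l2 >= h2) return false;
  *nlo = l2;
  *nhi = h2;
  if (v.bwt_at(hi - 1) == c) {
    *ntoe = toehold > 0 ? toehold - 1 : v.n - 1; // cyclic wrap at position 0
  } else {
    // the last c in [lo, hi) closes a run strictly inside the range
    int a = v.cr_off[c], b = v.cr_off[c + 1];
    // last c-run with start < hi
    while (a < b) {
      int mid = (a + b) / 2;
      if (v.run_start[v.cr_runs[mid]] >= hi) b = mid; else a = mid + 1;
    }
    int run = v.cr_runs[a - 1];
    *ntoe = v.sa_last[run] > 0 ? v.sa_last[run] - 1 : v.n - 1;
  }
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_backward_step(List idx, int lo, int hi, int toehold, RawVector ch) {
  IndexView v(idx);
  if (ch.size() != 1) stop("single character expected");
  int nlo, nhi, ntoe;
  if (lo >= hi || !backward_step_impl(v, lo, hi, toehold, ch[0], &nlo, &nhi, &ntoe))
    return IntegerVector::create(0, 0, NA_INTEGER);
  return IntegerVector::create(nlo, nhi, ntoe);
}

// [[Rcpp::export]]
IntegerVector cpp_pattern_search(List idx, RawVector pattern) {
  IndexView v(idx);
  int lo = 0, hi = v.n, toe = v.sa_last[v.r - 1];
  for (int i = pattern.size() - 1; i >= 0; --i) {
    int nlo, nhi, ntoe;
    if (!backward_step_impl(v, lo, hi, toe, pattern[i], &nlo, &nhi, &ntoe))
      return IntegerVector::create(0, 0, NA_INTEGER);
    lo = nlo; hi = nhi; toe = ntoe;
  }
  return IntegerVector::create(lo, hi, toe);
}

// Enumerate SA[lo..hi) from the toehold SA[hi-1] by repeated phi application.
// Results come out in row order hi-1 down to lo.
// [[Rcpp::export]]
IntegerVector cpp_locate(List idx, int lo, int hi, int toehold) {
  IndexView v(idx);
  if (lo >= hi) return IntegerVector(0);
  int k = hi - lo;
  IntegerVector out(k);
  int p = toehold;
  for (int i = 0; i < k; ++i) {
    out[i] = p;
    if (i + 1 < k) p = v.phi(p);
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_access(List idx, IntegerVector pos) {
  IndexView v(idx);
  RawVector out(pos.size());
  for (int i = 0; i < pos.size(); ++i) {
    if (pos[i] < 0 || pos[i] >= v.n) stop("position out of range");
    out[i] = v.text[pos[i]];
  }
  return out;
}

// [[Rcpp::export]]
int cpp_lf(List idx, int row) {
  IndexView v(idx);
  if (row < 0 || row >= v.n) stop("row out of range");
  return v.lf(row);
}

// [[Rcpp::export]]
List cpp_threshold_jump(List idx, int row, RawVector ch) {
  IndexView v(idx);
  int jrow, sa;
  bool ok = v.threshold_jump(row, ch[0], &jrow, &sa);
  return List::create(_["found"] = ok, _["row"] = jrow, _["toehold"] = sa);
}

// Two-pass matching statistics.  Backward pass walks the read right to left
// maintaining a single row whose suffix matches the current read suffix,
// using threshold jumps when the extension fails; it records one candidate
// text position per read position.  Forward pass measures the match lengths
// by direct text comparison.  Returns 0-based pos (-1 when no character of
// the read position can match at all) and lengths.
void matching_statistics_impl(const IndexView& v, const uint8_t* read, int m,
                              std::vector<int>& len, std::vector<int>& pos) {
  len.assign(m, 0);
  pos.assign(m, -1);
  int q = 0;               // row
  int p = v.sa_first[0];   // SA[0], the terminator suffix
  for (int i = m - 1; i >= 0; --i) {
    uint8_t c = read[i];
    if (!pm_is_acgt(c)) {
      // N never matches; reset to the terminator row
      q = 0;
      p = v.sa_first[0];
      pos[i] = -1;
      continue;
    }
    if (v.bwt_at(q) == c) {
      q = v.lf(q);
      p = p > 0 ? p - 1 : v.n - 1;
    } else {
      int jrow, sa;
      if (!v.threshold_jump(q, c, &jrow, &sa)) {
        q = 0;
        p = v.sa_first[0];
        pos[i] = -1;
        continue;
      }
      q = v.Ccum[c] + v.rank(c, jrow); // LF at jrow, whose BWT char is c
      p = sa > 0 ? sa - 1 : v.n - 1;
    }
    pos[i] = p;
  }
  // forward pass: lengths by direct comparison
  for (int i = 0; i < m; ++i) {
    if (pos[i] < 0) { len[i] = 0; continue; }
    int l = 0;
    while (i + l < m && pos[i] + l < v.n && pm_match(read[i + l], v.text[pos[i] + l]))
      ++l;
    len[i] = l;
    if (l == 0) pos[i] = -1;
  }
}

// [[Rcpp::export]]
List cpp_matching_statistics(List idx, RawVector read) {
  IndexView v(idx);
  int m = read.size();
  if (m == 0) stop("empty read");
  std::vector<int> len, pos;
  matching_statistics_impl(v, RAW(read), m, len, pos);
  return List::create(_["len"] = IntegerVector(len.begin(), len.end()),
                      _["pos"] = IntegerVector(pos.begin(), pos.end()));
}
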