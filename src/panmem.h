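#ifndef PANMEM_H
#define PANMEM_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

// Byte alphabet. The terminator must be the unique smallest byte of the
// indexed text; the separator sits between documents. Both are below every
// printable IUPAC byte so plain byte order gives the documented ordering
// terminator < separator < '#' < 'A' < 'C' < 'G' < 'N' < 'T'.
static const uint8_t PM_TERM = 0x01;
static const uint8_t PM_SEP  = 0x02;

inline bool pm_is_acgt(uint8_t c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Read-vs-text character equality: a read character only ever matches the
// identical A/C/G/T text character.  N (either side), separators and the
// terminator never match.
inline bool pm_match(uint8_t read_c, uint8_t text_c) {
  return read_c == text_c && pm_is_acgt(read_c);
}

inline uint8_t pm_comp(uint8_t c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct Scheme {
  int m1;        // match score
  int m2;        // mismatch penalty (positive)
  int gap_open;  // gap of length g costs gap_open + g * gap_ext
  int gap_ext;
};

inline Scheme scheme_from_list(Rcpp::List s) {
  Scheme sc;
  sc.m1 = Rcpp::as<int>(s["match"]);
  sc.m2 = Rcpp::as<int>(s["mismatch"]);
  sc.gap_open = Rcpp::as<int>(s["gap_open"]);
  sc.gap_ext = Rcpp::as<int>(s["gap_extend"]);
  return sc;
}

// CIGAR-like operation list. Ops: '=', 'X', 'M', 'I', 'D', 'S'.
struct OpList {
  std::vector<char> op;
  std::vector<int> len;
  void push(char o, int l) {
    if (l <= 0) return;
    if (!op.empty() && op.back() == o) len.back() += l;
    else { op.push_back(o); len.push_back(l); }
  }
  void append(const OpList& other) {
    for (size_t i = 0; i < other.op.size(); ++i) push(other.op[i], other.len[i]);
  }
  int read_len() const {
    int s = 0;
    for (size_t i = 0; i < op.size(); ++i)
      if (op[i] != 'D') s += len[i];
    return s;
  }
  int ref_len() const {
    int s = 0;
    for (size_t i = 0; i < op.size(); ++i)
      if (op[i] == 'M' || op[i] == '=' || op[i] == 'X' || op[i] == 'D') s += len[i];
    return s;
  }
};

// View over the index List built by cpp_build_rindex.  Vectors are borrowed
// from R memory; no copies are made.
struct IndexView {
  int n, r;
  const uint8_t* text;
  const uint8_t* run_char;
  const int* run_start;   // r entries, first row of each run
  const int* run_len;
  const int* sa_first;    // SA at first row of run
  const int* sa_last;     // SA at last row of run
  const int* Ccum;        // 257: Ccum[b] = #chars with byte < b
  const int* cr_off;      // 257 offsets into cr_* arrays
  const int* cr_runs;     // run ids grouped by character
  const int* cr_cum;      // count of this char before that run
  const int* cr_thresh;   // threshold row preceding this char-run (0 for first)
  const int* phi_key;     // sorted SA values at run starts (rows >= 1)
  const int* phi_val;     // SA value of the preceding row
  int phi_n;

  // Kept alive for the duration of the view.
  Rcpp::RawVector text_v, run_char_v;
  Rcpp::IntegerVector run_start_v, run_len_v, sa_first_v, sa_last_v, Ccum_v,
      cr_off_v, cr_runs_v, cr_cum_v, cr_thresh_v, phi_key_v, phi_val_v;

  explicit IndexView(Rcpp::List idx) {
    n = Rcpp::as<int>(idx["n"]);
    r = Rcpp::as<int>(idx["r"]);
    text_v = idx["text"];
    run_char_v = idx["run_char"];
    run_start_v = idx["run_start"];
    run_len_v = idx["run_len"];
    sa_first_v = idx["sa_first"];
    sa_last_v = idx["sa_last"];
    Ccum_v = idx["Ccum"];
    cr_off_v = idx["cr_off"];
    cr_runs_v = idx["cr_runs"];
    cr_cum_v = idx["cr_cum"];
    cr_thresh_v = idx["cr_thresh"];
    phi_key_v = idx["phi_key"];
    phi_val_v = idx["phi_val"];
    text = RAW(text_v);
    run_char = RAW(run_char_v);
    run_start = INTEGER(run_start_v);
    run_len = INTEGER(run_len_v);
    sa_first = INTEGER(sa_first_v);
    sa_last = INTEGER(sa_last_v);
    Ccum = INTEGER(Ccum_v);
    cr_off = INTEGER(cr_off_v);
    cr_runs = INTEGER(cr_runs_v);
    cr_cum = INTEGER(cr_cum_v);
    cr_thresh = INTEGER(cr_thresh_v);
    phi_key = INTEGER(phi_key_v);
    phi_val = INTEGER(phi_val_v);
    phi_n = phi_key_v.size();
  }

  int run_of_row(int row) const {
    // last run with run_start <= row
    int lo = 0, hi = r - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (run_start[mid] <= row) lo = mid; else hi = mid - 1;
    }
    return lo;
  }

  uint8_t bwt_at(int row) const { return run_char[run_of_row(row)]; }

  // number of occurrences of c in BWT[0..i)
  int rank(uint8_t c, int i) const {
    int lo = cr_off[c], hi = cr_off[c + 1];
    if (lo == hi || i <= 0) return 0;
    // first k in [lo,hi) with run_start[cr_runs[k]] >= i
    int a = lo, b = hi;
    while (a < b) {
      int mid = (a + b) / 2;
      if (run_start[cr_runs[mid]] >= i) b = mid; else a = mid + 1;
    }
    if (a == lo) return 0;
    int k = a - 1;
    int run = cr_runs[k];
    int extra = std::min(i - run_start[run], run_len[run]);
    return cr_cum[k] + extra;
  }

  int lf(int row) const {
    uint8_t c = bwt_at(row);
    return Ccum[c] + rank(c, row);
  }

  // SA[row - 1] given p = SA[row] (row >= 1): predecessor sample + offset.
  int phi(int p) const {
    int lo = 0, hi = phi_n - 1;
    // last key <= p
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (phi_key[mid] <= p) lo = mid; else hi = mid - 1;
    }
    return phi_val[lo] + (p - phi_key[lo]);
  }

  // When the backward step for c fails at `row`, pick the neighbouring c-run
  // to jump to.  Returns false when c has no run at all.
  bool threshold_jump(int row, uint8_t c, int* jrow, int* sa) const {
    int lo = cr_off[c], hi = cr_off[c + 1];
    if (lo == hi) return false;
    // first c-run with start > row
    int a = lo, b = hi;
    while (a < b) {
      int mid = (a + b) / 2;
      if (run_start[cr_runs[mid]] > row) b = mid; else a = mid + 1;
    }
    if (a == lo) {            // above the first c-run
      int run = cr_runs[lo];
      *jrow = run_start[run];
      *sa = sa_first[run];
    } else if (a == hi) {     // below the last c-run (or inside it)
      int run = cr_runs[hi - 1];
      int end_row = run_start[run] + run_len[run] - 1;
      if (row <= end_row) { *jrow = row; *sa = -1; return false; } // inside: caller bug
      *jrow = end_row;
      *sa = sa_last[run];
    } else {
      int prev = cr_runs[a - 1];
      int next = cr_runs[a];
      int prev_end = run_start[prev] + run_len[prev] - 1;
      if (row <= prev_end) { *jrow = row; *sa = -1; return false; }
      int t = cr_thresh[a];
      if (row < t) { *jrow = prev_end; *sa = sa_last[prev]; }
      else         { *jrow = run_start[next]; *sa = sa_first[next]; }
    }
    return true;
  }
};

inline Rcpp::CharacterVector ops_to_rchar(const std::vector<char>& v) {
  Rcpp::CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = std::string(1, v[i]);
  return out;
}

// Affine-gap alignment primitives (extend.cpp)
int gotoh_global(const uint8_t* a, int la, const uint8_t* b, int lb,
                 const Scheme& sc, OpList* ops);
int extend_flank(const uint8_t* a, int la, const uint8_t* b, int lb,
                 const Scheme& sc, OpList* ops, int* a_used, int* b_used);
int fit_align(const uint8_t* a, int la, const uint8_t* b, int lb,
              const Scheme& sc, OpList* ops, int* b_start);
int fill_between_impl(const uint8_t* rd, int m, const uint8_t* wn, int wlen,
                      std::vector<int> x, std::vector<int> y, std::vector<int> l,
                      const Scheme& sc, OpList* fin, int* win_start_out);

// rindex_query.cpp
void matching_statistics_impl(const IndexView& v, const uint8_t* read, int m,
                              std::vector<int>& len, std::vector<int>& pos);

// chain.cpp
struct ChainOut {
  std::vector<std::vector<int>> chains; // anchor indices (input order)
  std::vector<double> scores;
};
ChainOut chain_anchors_impl(const std::vector<int>& x, const std::vector<int>& y,
                            const std::vector<int>& l, double c1, double c2,
                            int max_gap, double min_score, int max_chains);

// lift.cpp
struct LiftSegs {
  // parallel arrays ordered along the haplotype; kind 0 = match,
  // 1 = insertion in haplotype (no reference bases), 2 = deletion in
  // haplotype (reference bases absent from the haplotype, zero hap length)
  const int* hs; const int* rs; const int* len; const int* kind; int nseg;
};
bool lift_ops_impl(const LiftSegs& L, int hap_start, const OpList& ops,
                   int* ref_start, OpList* out);
int lift_point_impl(const LiftSegs& L, int pos);

#endif
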