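#include "panmem.h"
using namespace Rcpp;

// Affine-gap dynamic programming (Gotoh).  A gap of length g costs
// gap_open + g * gap_ext.  Read and target are compared with pm_match, so N
// never matches anything.  Tracebacks use explicit per-cell direction flags:
//   bit 0-1: source of M (0 diag, 1 E, 2 F)
//   bit 2:   E opened from M (else continued)
//   bit 3:   F opened from M (else continued)

static const int NEG = -(1 << 28);

namespace {

struct DPResult {
  std::vector<int> M, E, F;
  std::vector<uint8_t> dir;
  int W;
};

// Fill the DP tables.  free_b_start: M[0][j] = 0 (fitting alignment);
// otherwise leading gaps are charged.
void dp_fill(const uint8_t* a, int la, const uint8_t* b, int lb,
             const Scheme& sc, bool free_b_start, DPResult* R) {
  int W = lb + 1;
  R->W = W;
  R->M.assign((la + 1) * W, NEG);
  R->E.assign((la + 1) * W, NEG);
  R->F.assign((la + 1) * W, NEG);
  R->dir.assign((la + 1) * W, 0);
  R->M[0] = 0;
  for (int j = 1; j <= lb; ++j) {
    if (free_b_start) R->M[j] = 0;
    else { R->E[j] = -(sc.gap_open + j * sc.gap_ext); R->M[j] = R->E[j]; R->dir[j] = 1; }
  }
  for (int i = 1; i <= la; ++i) {
    R->F[i * W] = -(sc.gap_open + i * sc.gap_ext);
    R->M[i * W] = R->F[i * W];
    R->dir[i * W] = 2;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int idx = i * W + j;
      uint8_t d = 0;
      int e_cont = R->E[idx - 1] - sc.gap_ext;
      int e_open = R->M[idx - 1] - sc.gap_open - sc.gap_ext;
      if (e_open >= e_cont) { R->E[idx] = e_open; d |= 4; } else R->E[idx] = e_cont;
      int f_cont = R->F[idx - W] - sc.gap_ext;
      int f_open = R->M[idx - W] - sc.gap_open - sc.gap_ext;
      if (f_open >= f_cont) { R->F[idx] = f_open; d |= 8; } else R->F[idx] = f_cont;
      int diag = R->M[idx - W - 1] + (pm_match(a[i - 1], b[j - 1]) ? sc.m1 : -sc.m2);
      int best = diag; uint8_t src = 0;
      if (R->E[idx] > best) { best = R->E[idx]; src = 1; }
      if (R->F[idx] > best) { best = R->F[idx]; src = 2; }
      R->M[idx] = best;
      R->dir[idx] = d | src;
    }
  }
}

// Trace back from cell (i, j) in state M to the table origin row/column.
// stop_at_free: stop when a free-start cell (i == 0) is reached.
void dp_traceback(const DPResult& R, const uint8_t* a, const uint8_t* b,
                  int i, int j, bool free_b_start, OpList* out, int* start_j) {
  OpList rev;
  int W = R.W;
  int state = R.dir[i * W + j] & 3;
  if (i == 0 && (j == 0 || free_b_start)) state = 0;
  while (true) {
    if (i == 0 && free_b_start) break;
    if (i == 0 && j == 0) break;
    int idx = i * W + j;
    if (i == 0) { rev.push('D', 1); --j; continue; }
    if (j == 0) { rev.push('I', 1); --i; continue; }
    if (state == 0) {
      rev.push(pm_match(a[i - 1], b[j - 1]) ? '=' : 'X', 1);
      --i; --j;
      state = R.dir[i * W + j] & 3;
      if (i == 0 && free_b_start) break;
      if (i == 0 && j == 0) break;
    } else if (state == 1) {
      rev.push('D', 1);
      bool opened = (R.dir[idx] & 4) != 0;
      --j;
      if (opened) state = R.dir[i * W + j] & 3;
    } else {
      rev.push('I', 1);
      bool opened = (R.dir[idx] & 8) != 0;
      --i;
      if (opened) state = R.dir[i * W + j] & 3;
    }
  }
  if (start_j) *start_j = j;
  for (int k = (int)rev.op.size() - 1; k >= 0; --k) out->push(rev.op[k], rev.len[k]);
}

} // namespace

// Global alignment: both sequences consumed entirely.  Returns the score and
// appends '='/'X'/'I'/'D' operations ('I' consumes read only).
int gotoh_global(const uint8_t* a, int la, const uint8_t* b, int lb,
                 const Scheme& sc, OpList* ops) {
  if (la == 0 && lb == 0) return 0;
  if (la == 0) { if (ops) ops->push('D', lb); return -(sc.gap_open + lb * sc.gap_ext); }
  if (lb == 0) { if (ops) ops->push('I', la); return -(sc.gap_open + la * sc.gap_ext); }
  DPResult R;
  dp_fill(a, la, b, lb, sc, false, &R);
  int score = R.M[la * R.W + lb];
  if (ops) dp_traceback(R, a, b, la, lb, false, ops, nullptr);
  return score;
}

// Extension alignment anchored at (0, 0): the best-scoring cell wins and the
// unaligned read remainder is left for the caller to soft-clip.  Ties prefer
// consuming more read, then more target.  Returns the best score (0 means
// extend nothing; negative-score extensions are clipped away).
int extend_flank(const uint8_t* a, int la, const uint8_t* b, int lb,
                 const Scheme& sc, OpList* ops, int* a_used, int* b_used) {
  *a_used = 0; *b_used = 0;
  if (la == 0 || lb == 0) return 0;
  DPResult R;
  dp_fill(a, la, b, lb, sc, false, &R);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i)
    for (int j = 1; j <= lb; ++j) {
      int v = R.M[i * R.W + j];
      if (v > best || (v == best && (i > bi || (i == bi && j > bj)))) {
        best = v; bi = i; bj = j;
      }
    }
  if (best <= 0) return 0;
  *a_used = bi; *b_used = bj;
  if (ops) dp_traceback(R, a, b, bi, bj, false, ops, nullptr);
  return best;
}

// Fitting alignment: the read is consumed globally, the target window start
// and end are free (orphan recovery inside the insert window).  b_start
// receives the window offset where the alignment begins.
int fit_align(const uint8_t* a, int la, const uint8_t* b, int lb,
              const Scheme& sc, OpList* ops, int* b_start) {
  *b_start = 0;
  if (la == 0 || lb == 0) return NEG;
  DPResult R;
  dp_fill(a, la, b, lb, sc, true, &R);
  int best = NEG, bj = 0;
  for (int j = 0; j <= lb; ++j)
    if (R.M[la * R.W + j] > best) { best = R.M[la * R.W + j]; bj = j; }
  OpList tmp;
  dp_traceback(R, a, b, la, bj, true, &tmp, b_start);
  if (ops) ops->append(tmp);
  return best;
}

// [[Rcpp::export]]
List cpp_gotoh_global(RawVector a, RawVector b, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  OpList ops;
  int score = gotoh_global(RAW(a), a.size(), RAW(b), b.size(), sc, &ops);
  return List::create(_["score"] = score,
                      _["op"] = ops_to_rchar(ops.op),
                      _["len"] = IntegerVector(ops.len.begin(), ops.len.end()));
}

// [[Rcpp::export]]
List cpp_fit_align(RawVector a, RawVector b, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  OpList ops;
  int bstart;
  int score = fit_align(RAW(a), a.size(), RAW(b), b.size(), sc, &ops, &bstart);
  return List::create(_["score"] = score, _["b_start"] = bstart,
                      _["op"] = ops_to_rchar(ops.op),
                      _["len"] = IntegerVector(ops.len.begin(), ops.len.end()));
}

// Anchored gap-filling shared by the R surface and the batch pipeline.
int fill_between_impl(const uint8_t* rd, int m, const uint8_t* wn, int wlen,
                      std::vector<int> x, std::vector<int> y, std::vector<int> l,
                      const Scheme& sc, OpList* fin, int* win_start_out) {
  int k = (int)x.size();
  std::vector<int> keep;
  int px = -1, py = -1;
  for (int i = 0; i < k; ++i) {
    if (!keep.empty()) {
      int t = std::max(0, std::max(px - x[i], py - y[i]));
      if (t >= l[i]) continue;
      x[i] += t; y[i] += t; l[i] -= t;
    }
    keep.push_back(i);
    px = x[i] + l[i]; py = y[i] + l[i];
  }
  if (keep.empty()) stop("anchors collapsed after trimming");
  for (int kk : keep) {
    if (x[kk] < 0 || x[kk] + l[kk] > m || y[kk] < 0 || y[kk] + l[kk] > wlen)
      stop("anchor outside read/window");
    for (int t = 0; t < l[kk]; ++t)
      if (!pm_match(rd[x[kk] + t], wn[y[kk] + t]))
        stop("anchor is not an exact match");
  }

  OpList ops;
  int score = 0;
  int first = keep.front(), last = keep.back();

  int lead_clip = x[first];
  int win_start = y[first];
  if (x[first] > 0) {
    std::vector<uint8_t> ar(rd, rd + x[first]);
    std::reverse(ar.begin(), ar.end());
    std::vector<uint8_t> br(wn, wn + y[first]);
    std::reverse(br.begin(), br.end());
    OpList fo;
    int aused, bused;
    score += extend_flank(ar.data(), (int)ar.size(), br.data(), (int)br.size(),
                          sc, &fo, &aused, &bused);
    lead_clip = x[first] - aused;
    win_start = y[first] - bused;
    if (aused > 0 || bused > 0) {
      std::reverse(fo.op.begin(), fo.op.end());
      std::reverse(fo.len.begin(), fo.len.end());
      OpList tmp;
      for (size_t t = 0; t < fo.op.size(); ++t) tmp.push(fo.op[t], fo.len[t]);
      ops.append(tmp);
    }
  }

  for (size_t ki = 0; ki < keep.size(); ++ki) {
    int i = keep[ki];
    if (ki > 0) {
      int ip = keep[ki - 1];
      OpList go;
      score += gotoh_global(rd + x[ip] + l[ip], x[i] - (x[ip] + l[ip]),
                            wn + y[ip] + l[ip], y[i] - (y[ip] + l[ip]), sc, &go);
      ops.append(go);
    }
    ops.push('=', l[i]);
    score += sc.m1 * l[i];
  }

  int tail_clip = m - (x[last] + l[last]);
  if (tail_clip > 0) {
    OpList fo;
    int aused, bused;
    score += extend_flank(rd + x[last] + l[last], tail_clip,
                          wn + y[last] + l[last], wlen - (y[last] + l[last]),
                          sc, &fo, &aused, &bused);
    ops.append(fo);
    tail_clip -= aused;
  }

  if (lead_clip > 0) fin->push('S', lead_clip);
  fin->append(ops);
  if (tail_clip > 0) fin->push('S', tail_clip);
  *win_start_out = win_start;
  return score;
}

// [[Rcpp::export]]
List cpp_fill_between(RawVector read, RawVector window, IntegerVector ax,
                      IntegerVector ay, IntegerVector al, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  if (ax.size() == 0) stop("no anchors");
  OpList fin;
  int win_start;
  int score = fill_between_impl(
      RAW(read), read.size(), RAW(window), window.size(),
      std::vector<int>(ax.begin(), ax.end()),
      std::vector<int>(ay.begin(), ay.end()),
      std::vector<int>(al.begin(), al.end()), sc, &fin, &win_start);
  return List::create(_["score"] = score, _["win_start"] = win_start,
                      _["op"] = ops_to_rchar(fin.op),
                      _["len"] = IntegerVector(fin.len.begin(), fin.len.end()));
}

// Re-score a CIGAR from scratch against the read and the target window
// (consistency checker).  M ops are re-classified by comparing characters.
// [[Rcpp::export]]
int cpp_score_cigar(CharacterVector op, IntegerVector len, RawVector read,
                    RawVector window, List scheme) {
  Scheme sc = scheme_from_list(scheme);
  if (op.size() == 0) stop("empty CIGAR");
  const uint8_t* rd = RAW(read);
  const uint8_t* wn = RAW(window);
  int i = 0, j = 0, score = 0;
  for (int k = 0; k < op.size(); ++k) {
    char o = CHAR(STRING_ELT(op, k))[0];
    int L = len[k];
    if (L <= 0) stop("non-positive CIGAR length");
    switch (o) {
      case 'M': case '=': case 'X':
        for (int t = 0; t < L; ++t) {
          if (i >= (int)read.size() || j >= (int)window.size())
            stop("CIGAR overruns read or window");
          bool eq = pm_match(rd[i], wn[j]);
          if (o == '=' && !eq) stop("'=' op over mismatching bases");
          if (o == 'X' && eq) stop("'X' op over matching bases");
          score += eq ? sc.m1 : -sc.m2;
          ++i; ++j;
        }
        break;
      case 'I':
        score -= sc.gap_open + L * sc.gap_ext; i += L; break;
      case 'D':
        score -= sc.gap_open + L * sc.gap_ext; j += L; break;
      case 'S':
        i += L; break;
      default:
        stop("unsupported CIGAR op");
    }
  }
  if (i != (int)read.size()) stop("CIGAR does not consume the read exactly");
  return score;
}
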