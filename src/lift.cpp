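#include "panmem.h"
using namespace Rcpp;

// Haplotype -> reference coordinate lifting through variant-derived segment
// maps.  Only indels break match segments (SNPs preserve coordinates), so a
// lift map is: match segments (kind 0), insertions in the haplotype (kind 1,
// haplotype bases without reference counterpart) and deletions in the
// haplotype (kind 2, zero haplotype width, len reference bases skipped).

// Reference position of a haplotype position; positions inside an insertion
// anchor to the reference position the insertion is attached to.  -1 when
// the position is not covered.
int lift_point_impl(const LiftSegs& L, int pos) {
  for (int i = 0; i < L.nseg; ++i) {
    if (L.kind[i] == 2) continue;
    if (pos >= L.hs[i] && pos < L.hs[i] + L.len[i])
      return L.kind[i] == 0 ? L.rs[i] + (pos - L.hs[i]) : L.rs[i];
  }
  return -1;
}

// Rewrite alignment operations (read vs haplotype) into read vs reference.
// Returns false when no reference-consuming op survives (alignment sits
// entirely inside a haplotype insertion -> unliftable).
bool lift_ops_impl(const LiftSegs& L, int hap_start, const OpList& ops,
                   int* ref_start, OpList* out) {
  struct Piece { char op; int len; int ref; };
  std::vector<Piece> pieces;
  int h = hap_start;
  int si = 0;
  bool started = false; // some haplotype base already consumed
  // skip segments wholly before hap_start
  while (si < L.nseg &&
         ((L.kind[si] == 2 && L.hs[si] <= hap_start) ||
          (L.kind[si] != 2 && L.hs[si] + L.len[si] <= hap_start)))
    ++si;
  for (size_t k = 0; k < ops.op.size(); ++k) {
    char o = ops.op[k];
    int len = ops.len[k];
    if (o == 'S' || o == 'I') {
      pieces.push_back({o, len, -1});
      continue;
    }
    // op consumes haplotype ('M', '=', 'X', 'D')
    int remaining = len;
    while (remaining > 0) {
      while (si < L.nseg && L.kind[si] == 2) {
        if (started) pieces.push_back({'D', L.len[si], -1});
        ++si;
      }
      if (si >= L.nseg) stop("alignment runs past the lift map");
      int seg_end = L.hs[si] + L.len[si];
      if (h < L.hs[si]) stop("lift map does not tile the haplotype");
      int take = std::min(remaining, seg_end - h);
      if (take <= 0) stop("internal error in lift segment walk");
      if (L.kind[si] == 0) {
        pieces.push_back({o, take, L.rs[si] + (h - L.hs[si])});
      } else { // insertion in haplotype
        if (o != 'D') pieces.push_back({'I', take, -1});
        // 'D' over inserted bases consumes neither read nor reference
      }
      started = true;
      h += take;
      remaining -= take;
      if (h == seg_end) ++si;
    }
  }
  // trim: leading/trailing D dropped, leading/trailing I folded into S
  int lo = 0, hi = (int)pieces.size();
  auto is_edge = [](char o) { return o == 'S' || o == 'I' || o == 'D'; };
  while (lo < hi && is_edge(pieces[lo].op)) ++lo;
  while (hi > lo && is_edge(pieces[hi - 1].op)) --hi;
  if (lo >= hi) return false;
  int lead_clip = 0, tail_clip = 0;
  for (int i = 0; i < lo; ++i)
    if (pieces[i].op != 'D') lead_clip += pieces[i].len;
  for (int i = hi; i < (int)pieces.size(); ++i)
    if (pieces[i].op != 'D') tail_clip += pieces[i].len;
  *ref_start = pieces[lo].ref;
  if (lead_clip > 0) out->push('S', lead_clip);
  for (int i = lo; i < hi; ++i) out->push(pieces[i].op, pieces[i].len);
  if (tail_clip > 0) out->push('S', tail_clip);
  return true;
}

// [[Rcpp::export]]
int cpp_lift_point(IntegerVector hs, IntegerVector rs, IntegerVector len,
                   IntegerVector kind, int pos) {
  LiftSegs L{INTEGER(hs), INTEGER(rs), INTEGER(len), INTEGER(kind), (int)hs.size()};
  return lift_point_impl(L, pos);
}

// [[Rcpp::export]]
List cpp_lift_ops(IntegerVector hs, IntegerVector rs, IntegerVector len,
                  IntegerVector kind, int hap_start, CharacterVector op,
                  IntegerVector oplen) {
  LiftSegs L{INTEGER(hs), INTEGER(rs), INTEGER(len), INTEGER(kind), (int)hs.size()};
  OpList ops;
  for (int k = 0; k < op.size(); ++k)
    ops.push(CHAR(STRING_ELT(op, k))[0], oplen[k]);
  OpList out;
  int ref_start = -1;
  bool ok = lift_ops_impl(L, hap_start, ops, &ref_start, &out);
  return List::create(_["liftable"] = ok, _["ref_start"] = ref_start,
                      _["op"] = ops_to_rchar(out.op),
                      _["len"] = IntegerVector(out.len.begin(), out.len.end()));
}
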