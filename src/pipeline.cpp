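#include "panmem.h"
#include <map>
#include <set>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small numeric helpers shared with the R surface
// ---------------------------------------------------------------------------

int mapq_single_impl(double s1, double s2, int n, int len, int m1, int m2) {
  double i = 1.0 - ((double)m1 * len - s1) / ((double)(m1 + m2) * len);
  if (i < 0) i = 0;
  if (i > 1) i = 1;
  double Q = 6.02 * (s1 - s2) * i / (4.0 * m1) - 4.343 * std::log((double)n + 1.0);
  if (Q > 60.0) Q = 60.0;
  int q = (int)Q; // truncate
  if (q < 0) q = 0;
  if (q > 60) q = 60;
  return q;
}

int mapq_paired_impl(int Q, int Qp, double s1p, double s2p, int m1) {
  double inner = std::max((double)Q, std::min((double)Qp, (double)Q + 40.0));
  double cap = 6.02 * (s1p - s2p) / (double)m1;
  double Qi = std::min(inner, cap);
  int q = (int)Qi;
  if (q < 0) q = 0;
  if (q > 60) q = 60;
  return q;
}

int count_secondary_impl(const std::vector<double>& scores, double s1, double frac) {
  std::set<double> distinct;
  for (double s : scores)
    if (s < s1 && s >= frac * s1) distinct.insert(s);
  return (int)distinct.size();
}

// [[Rcpp::export]]
int cpp_mapq_single(double s1, double s2, int n, int len, int m1, int m2) {
  return mapq_single_impl(s1, s2, n, len, m1, m2);
}

// [[Rcpp::export]]
int cpp_mapq_paired(int Q, int Qp, double s1p, double s2p, int m1) {
  return mapq_paired_impl(Q, Qp, s1p, s2p, m1);
}

// [[Rcpp::export]]
int cpp_count_secondary(NumericVector scores, double s1, double frac) {
  std::vector<double> v(scores.begin(), scores.end());
  return count_secondary_impl(v, s1, frac);
}

// Welford's online mean/variance.
struct Welford {
  long long count = 0;
  double mean = 0.0, M2 = 0.0;
  void update(double x) {
    ++count;
    double d = x - mean;
    mean += d / count;
    M2 += d * (x - mean);
  }
  double var() const { return count > 1 ? M2 / (count - 1) : R_NaN; }
  double sd() const { return count > 1 ? std::sqrt(var()) : R_NaN; }
};

// [[Rcpp::export]]
List cpp_welford(NumericVector x) {
  Welford w;
  for (double v : x) w.update(v);
  return List::create(_["count"] = (double)w.count, _["mean"] = w.mean,
                      _["M2"] = w.M2, _["sd"] = w.sd(), _["var"] = w.var());
}

// ---------------------------------------------------------------------------
// configuration / reference bundles
// ---------------------------------------------------------------------------

struct AlnCfg {
  int min_mem_len, split_threshold, max_occ_per_genome;
  bool freq_on; double freq_frac;
  bool orient_on; int orient_gap;
  double chain_min_score; int max_chains, max_gap;
  double chain_c1, chain_c2;
  bool uniq_on;
  Scheme sc;
  bool orphan_on; double orphan_floor_frac;
  int max_is_pairs; double nsec_frac;
  bool emit_eqx;
};

static AlnCfg cfg_from_list(List cfg) {
  AlnCfg c;
  c.min_mem_len = as<int>(cfg["min_mem_len"]);
  c.split_threshold = as<int>(cfg["split_threshold"]);
  c.max_occ_per_genome = as<int>(cfg["max_occ_per_genome"]);
  c.freq_on = as<bool>(cfg["freq_filter"]);
  c.freq_frac = as<double>(cfg["freq_fraction"]);
  c.orient_on = as<bool>(cfg["orientation_filter"]);
  c.orient_gap = as<int>(cfg["orientation_gap"]);
  c.chain_min_score = as<double>(cfg["min_chain_score"]);
  c.max_chains = as<int>(cfg["max_chains"]);
  c.max_gap = as<int>(cfg["max_gap"]);
  c.chain_c1 = as<double>(cfg["chain_c1"]);
  c.chain_c2 = as<double>(cfg["chain_c2"]);
  c.uniq_on = as<bool>(cfg["uniqueness_filter"]);
  c.sc.m1 = as<int>(cfg["match"]);
  c.sc.m2 = as<int>(cfg["mismatch"]);
  c.sc.gap_open = as<int>(cfg["gap_open"]);
  c.sc.gap_ext = as<int>(cfg["gap_extend"]);
  c.orphan_on = as<bool>(cfg["orphan_recovery"]);
  c.orphan_floor_frac = as<double>(cfg["orphan_floor_frac"]);
  c.max_is_pairs = as<int>(cfg["max_insert_pairs"]);
  c.nsec_frac = as<double>(cfg["secondary_fraction"]);
  c.emit_eqx = as<bool>(cfg["emit_eqx"]);
  return c;
}

struct PGView {
  const int* doc_start; const int* doc_len; const int* genome; int n_docs;
  IntegerVector ds_v, dl_v, g_v;
  explicit PGView(List pg) {
    ds_v = pg["doc_start"]; dl_v = pg["doc_len"]; g_v = pg["genome_of_doc"];
    doc_start = INTEGER(ds_v); doc_len = INTEGER(dl_v); genome = INTEGER(g_v);
    n_docs = ds_v.size();
  }
  int doc_of(int g) const {
    int lo = 0, hi = n_docs - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (doc_start[mid] <= g) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

struct LiftView {
  IntegerVector off_v, hs_v, rs_v, len_v, kind_v, contig_v;
  const int* off; const int* hs; const int* rs; const int* len; const int* kind;
  const int* contig;
  explicit LiftView(List lf) {
    off_v = lf["seg_off"]; hs_v = lf["hs"]; rs_v = lf["rs"];
    len_v = lf["len"]; kind_v = lf["kind"]; contig_v = lf["doc_contig"];
    off = INTEGER(off_v); hs = INTEGER(hs_v); rs = INTEGER(rs_v);
    len = INTEGER(len_v); kind = INTEGER(kind_v); contig = INTEGER(contig_v);
  }
  LiftSegs segs(int doc) const {
    LiftSegs L;
    L.hs = hs + off[doc]; L.rs = rs + off[doc]; L.len = len + off[doc];
    L.kind = kind + off[doc]; L.nseg = off[doc + 1] - off[doc];
    return L;
  }
};

struct RefView {
  IntegerVector off_v; RawVector seq_v;
  const int* off; const uint8_t* seq; int n_contigs;
  explicit RefView(List rf) {
    off_v = rf["contig_off"]; seq_v = rf["seq"];
    off = INTEGER(off_v); seq = RAW(seq_v); n_contigs = off_v.size() - 1;
  }
  const uint8_t* contig_seq(int c) const { return seq + off[c]; }
  int contig_len(int c) const { return off[c + 1] - off[c]; }
};

// ---------------------------------------------------------------------------
// candidate generation
// ---------------------------------------------------------------------------

struct SeedS {
  int x, len, strand;               // strand 0 fwd, 1 rc
  std::vector<std::pair<int,int>> occ; // (doc, local)
  long long total_uncapped;
};

struct Cand {
  int doc = 0, strand = 0, hap_start = 0;
  double score = 0;
  OpList hops;
  int contig = 0, rpos = 0, rspan = 0, nm = 0, nx = 0;
  OpList rops;
};

static std::vector<uint8_t> normalize_read(const char* s) {
  std::vector<uint8_t> out;
  for (const char* p = s; *p; ++p) {
    char c = std::toupper(*p);
    out.push_back(pm_is_acgt((uint8_t)c) ? (uint8_t)c : (uint8_t)'N');
  }
  return out;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[v.size() - 1 - i] = pm_comp(v[i]);
  return out;
}

// MEM starts: len[i] >= min_len and (i == 0 or len[i-1] <= len[i])
void extract_mems_impl(const std::vector<int>& len, int min_len,
                       std::vector<std::pair<int,int>>* out) {
  for (size_t i = 0; i < len.size(); ++i)
    if (len[i] >= min_len && (i == 0 || len[i - 1] <= len[i]))
      out->push_back(std::make_pair((int)i, len[i]));
}

// [[Rcpp::export]]
List cpp_extract_mems(IntegerVector len, int min_len) {
  std::vector<int> lv(len.begin(), len.end());
  std::vector<std::pair<int,int>> mems;
  extract_mems_impl(lv, min_len, &mems);
  IntegerVector s(mems.size()), l(mems.size());
  for (size_t i = 0; i < mems.size(); ++i) { s[i] = mems[i].first + 1; l[i] = mems[i].second; }
  return List::create(_["start"] = s, _["len"] = l);
}

// locate one seed with the per-genome occurrence cap
static void locate_seed(const IndexView& v, const PGView& pg,
                        const uint8_t* seq, int len, int cap, SeedS* seed) {
  int lo = 0, hi = v.n, toe = v.sa_last[v.r - 1];
  for (int i = len - 1; i >= 0; --i) {
    uint8_t c = seq[i];
    int l2 = v.Ccum[c] + v.rank(c, lo);
    int h2 = v.Ccum[c] + v.rank(c, hi);
    if (l2 >= h2) { seed->total_uncapped = 0; return; }
    if (v.bwt_at(hi - 1) == c) toe = toe > 0 ? toe - 1 : v.n - 1;
    else {
      int a = v.cr_off[c], b = v.cr_off[c + 1];
      while (a < b) {
        int mid = (a + b) / 2;
        if (v.run_start[v.cr_runs[mid]] >= hi) b = mid; else a = mid + 1;
      }
      int s = v.sa_last[v.cr_runs[a - 1]];
      toe = s > 0 ? s - 1 : v.n - 1;
    }
    lo = l2; hi = h2;
  }
  seed->total_uncapped = hi - lo;
  long long k = hi - lo;
  const long long enum_bound = 500000; // safety valve for pathological seeds
  if (k > enum_bound) k = enum_bound;
  std::map<int,int> per_genome;
  int p = toe;
  for (long long i = 0; i < k; ++i) {
    int doc = pg.doc_of(p);
    int local = p - pg.doc_start[doc];
    if (local + len <= pg.doc_len[doc]) {
      int g = pg.genome[doc];
      if (per_genome[g] < cap) {
        per_genome[g]++;
        seed->occ.push_back(std::make_pair(doc, local));
      }
    }
    if (i + 1 < k) p = v.phi(p);
  }
  std::sort(seed->occ.begin(), seed->occ.end());
}

// seeds for one read (both strands), after occurrence cap + frequency +
// orientation filters
static void gen_seeds(const IndexView& v, const PGView& pg, const AlnCfg& cfg,
                      const std::vector<uint8_t>& fwd,
                      std::vector<SeedS>* seeds) {
  std::vector<uint8_t> oriented[2];
  oriented[0] = fwd;
  oriented[1] = revcomp(fwd);
  for (int st = 0; st < 2; ++st) {
    const std::vector<uint8_t>& rd = oriented[st];
    std::vector<int> len, pos;
    matching_statistics_impl(v, rd.data(), (int)rd.size(), len, pos);
    std::vector<std::pair<int,int>> mems;
    extract_mems_impl(len, cfg.min_mem_len, &mems);
    // split long MEMs into two halves, re-located independently
    std::vector<std::pair<int,int>> parts;
    for (auto& mm : mems) {
      if (mm.second > cfg.split_threshold) {
        int h1 = (mm.second + 1) / 2;
        parts.push_back(std::make_pair(mm.first, h1));
        parts.push_back(std::make_pair(mm.first + h1, mm.second - h1));
      } else parts.push_back(mm);
    }
    for (auto& pp : parts) {
      SeedS s;
      s.x = pp.first; s.len = pp.second; s.strand = st;
      s.total_uncapped = 0;
      locate_seed(v, pg, rd.data() + pp.first, pp.second,
                  cfg.max_occ_per_genome, &s);
      if (!s.occ.empty()) seeds->push_back(s);
    }
  }
  // frequency filter: drop seeds holding >= freq_frac of all occurrences
  if (cfg.freq_on && seeds->size() > 1) {
    long long total = 0;
    for (auto& s : *seeds) total += (long long)s.occ.size();
    if (total > 0) {
      std::vector<SeedS> kept;
      for (auto& s : *seeds)
        if ((double)s.occ.size() < cfg.freq_frac * (double)total)
          kept.push_back(s);
      if (!kept.empty()) *seeds = kept;
    }
  }
  // orientation filter: drop the strand with clearly smaller MEMs
  if (cfg.orient_on) {
    double sum[2] = {0, 0}; int cnt[2] = {0, 0};
    for (auto& s : *seeds) { sum[s.strand] += s.len; cnt[s.strand]++; }
    if (cnt[0] > 0 && cnt[1] > 0) {
      double m0 = sum[0] / cnt[0], m1 = sum[1] / cnt[1];
      if (std::abs(m0 - m1) >= cfg.orient_gap) {
        int drop = m0 < m1 ? 0 : 1;
        std::vector<SeedS> kept;
        for (auto& s : *seeds) if (s.strand != drop) kept.push_back(s);
        *seeds = kept;
      }
    }
  }
}

struct ChainRec {
  double score;
  int doc, strand;
  std::vector<int> ax, ay, al; // absolute read x, doc-local y, length
};

static void candidates_for_read(const IndexView& v, const PGView& pg,
                                const LiftView& lf, const RefView& rf,
                                const AlnCfg& cfg,
                                const std::vector<uint8_t>& fwd,
                                std::vector<Cand>* out) {
  int m = (int)fwd.size();
  std::vector<SeedS> seeds;
  gen_seeds(v, pg, cfg, fwd, &seeds);
  if (seeds.empty()) return;

  // group anchors by (doc, strand)
  std::map<std::pair<int,int>, std::vector<std::array<int,3>>> groups;
  for (auto& s : seeds)
    for (auto& oc : s.occ)
      groups[std::make_pair(oc.first, s.strand)].push_back({s.x, oc.second, s.len});

  std::vector<ChainRec> chains;
  for (auto& kv : groups) {
    auto& an = kv.second;
    std::vector<int> x, y, l;
    for (auto& a : an) { x.push_back(a[0]); y.push_back(a[1]); l.push_back(a[2]); }
    ChainOut co = chain_anchors_impl(x, y, l, cfg.chain_c1, cfg.chain_c2,
                                     cfg.max_gap, cfg.chain_min_score,
                                     cfg.max_chains);
    for (size_t ci = 0; ci < co.chains.size(); ++ci) {
      ChainRec cr;
      cr.score = co.scores[ci];
      cr.doc = kv.first.first;
      cr.strand = kv.first.second;
      for (int ai : co.chains[ci]) {
        cr.ax.push_back(x[ai]); cr.ay.push_back(y[ai]); cr.al.push_back(l[ai]);
      }
      chains.push_back(cr);
    }
  }
  if (chains.empty()) return;
  std::sort(chains.begin(), chains.end(), [](const ChainRec& a, const ChainRec& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.doc != b.doc) return a.doc < b.doc;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.ay.front() < b.ay.front();
  });
  if ((int)chains.size() > cfg.max_chains) chains.resize(cfg.max_chains);

  // uniqueness heuristic: equal (score, lifted leftmost anchor) => discard
  if (cfg.uniq_on) {
    std::set<std::pair<double, long long>> seen;
    std::vector<ChainRec> kept;
    for (auto& ch : chains) {
      LiftSegs L = lf.segs(ch.doc);
      int lifted = lift_point_impl(L, ch.ay.front());
      long long key = (long long)lf.contig[ch.doc] * (1LL << 40) + lifted;
      if (seen.insert(std::make_pair(ch.score, key)).second) kept.push_back(ch);
    }
    chains = kept;
  }

  const std::vector<uint8_t> rc = revcomp(fwd);
  for (auto& ch : chains) {
    const uint8_t* rd = (ch.strand == 0 ? fwd.data() : rc.data());
    const int pad = 32;
    int y_first = ch.ay.front(), x_first = ch.ax.front();
    int y_last = ch.ay.back(), x_last = ch.ax.back(), l_last = ch.al.back();
    int wlo = std::max(0, y_first - x_first - pad);
    int whi = std::min(pg.doc_len[ch.doc],
                       y_last + l_last + (m - x_last - l_last) + pad);
    const uint8_t* wn = v.text + pg.doc_start[ch.doc] + wlo;
    std::vector<int> ax(ch.ax), ay(ch.al.size()), al(ch.al);
    for (size_t i = 0; i < ch.ay.size(); ++i) ay[i] = ch.ay[i] - wlo;
    OpList hops;
    int win_start;
    int score = fill_between_impl(rd, m, wn, whi - wlo, ax, ay, al,
                                  cfg.sc, &hops, &win_start);
    Cand cd;
    cd.doc = ch.doc; cd.strand = ch.strand;
    cd.hap_start = wlo + win_start;
    cd.score = score;
    cd.hops = hops;
    // liftover
    LiftSegs L = lf.segs(ch.doc);
    OpList rops;
    int ref_start = -1;
    if (!lift_ops_impl(L, cd.hap_start, hops, &ref_start, &rops))
      continue; // no reference anchor: not representable on the reference
    cd.contig = lf.contig[ch.doc];
    cd.rpos = ref_start;
    cd.rops = rops;
    cd.rspan = rops.ref_len();
    // NM/mismatch count against the reference
    {
      const uint8_t* ref = rf.contig_seq(cd.contig);
      int i = 0, j = ref_start, nm = 0, nx = 0;
      for (size_t k = 0; k < rops.op.size(); ++k) {
        char o = rops.op[k]; int L2 = rops.len[k];
        if (o == 'M' || o == '=' || o == 'X') {
          for (int t = 0; t < L2; ++t) {
            if (!pm_match(rd[i + t], ref[j + t])) { ++nm; ++nx; }
          }
          i += L2; j += L2;
        } else if (o == 'I') { nm += L2; i += L2; }
        else if (o == 'D') { nm += L2; j += L2; }
        else if (o == 'S') { i += L2; }
      }
      cd.nm = nm; cd.nx = nx;
    }
    out->push_back(cd);
  }

  // order by score, then deterministic keys; dedup same lifted position
  std::sort(out->begin(), out->end(), [](const Cand& a, const Cand& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.rpos != b.rpos) return a.rpos < b.rpos;
    if (a.strand != b.strand) return a.strand < b.strand;
    return a.doc < b.doc;
  });
  std::set<std::tuple<int,int,int>> seen;
  std::vector<Cand> dedup;
  for (auto& c : *out)
    if (seen.insert(std::make_tuple(c.contig, c.rpos, c.strand)).second)
      dedup.push_back(c);
  *out = dedup;
}

// ---------------------------------------------------------------------------
// pairing
// ---------------------------------------------------------------------------

// Choose the best valid combination: same contig, opposite strands, outer
// distance within [mu - 4 sigma, mu + 4 sigma] (a hard constraint).
// Returns (i, j) 0-based into the candidate lists, or (-1, -1).
static void pair_select_impl(const std::vector<Cand>& c1,
                             const std::vector<Cand>& c2,
                             double mu, double sigma, bool model_ok,
                             int* bi, int* bj, double* s1p, double* s2p,
                             std::vector<double>* pair_scores) {
  *bi = -1; *bj = -1; *s1p = 0; *s2p = 0;
  if (!model_ok) return;
  double lo = mu - 4.0 * sigma, hi = mu + 4.0 * sigma;
  double best = -1e18, second = -1e18;
  for (size_t i = 0; i < c1.size(); ++i)
    for (size_t j = 0; j < c2.size(); ++j) {
      if (c1[i].contig != c2[j].contig) continue;
      if (c1[i].strand == c2[j].strand) continue;
      int a0 = c1[i].rpos, a1 = c1[i].rpos + c1[i].rspan;
      int b0 = c2[j].rpos, b1 = c2[j].rpos + c2[j].rspan;
      int outer = std::max(a1, b1) - std::min(a0, b0);
      if (outer < lo || outer > hi) continue;
      double s = c1[i].score + c2[j].score;
      pair_scores->push_back(s);
      if (s > best) { second = best; best = s; *bi = (int)i; *bj = (int)j; }
      else if (s > second) second = s;
    }
  if (*bi >= 0) { *s1p = best; *s2p = second > -1e17 ? second : 0.0; }
}

// [[Rcpp::export]]
List cpp_pair_select(IntegerVector contig1, IntegerVector pos1, IntegerVector span1,
                     IntegerVector strand1, NumericVector score1,
                     IntegerVector contig2, IntegerVector pos2, IntegerVector span2,
                     IntegerVector strand2, NumericVector score2,
                     double mu, double sigma) {
  std::vector<Cand> c1(contig1.size()), c2(contig2.size());
  for (int i = 0; i < contig1.size(); ++i) {
    c1[i].contig = contig1[i]; c1[i].rpos = pos1[i]; c1[i].rspan = span1[i];
    c1[i].strand = strand1[i]; c1[i].score = score1[i];
  }
  for (int i = 0; i < contig2.size(); ++i) {
    c2[i].contig = contig2[i]; c2[i].rpos = pos2[i]; c2[i].rspan = span2[i];
    c2[i].strand = strand2[i]; c2[i].score = score2[i];
  }
  int bi, bj; double s1p, s2p;
  std::vector<double> ps;
  pair_select_impl(c1, c2, mu, sigma, true, &bi, &bj, &s1p, &s2p, &ps);
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1, _["s1p"] = s1p,
                      _["s2p"] = s2p);
}

// ---------------------------------------------------------------------------
// batch alignment
// ---------------------------------------------------------------------------

struct MateRes {
  bool mapped = false;
  Cand aln;
  int mapq = 0;
  double s1 = 0, s2 = 0;
  int nsec = 0;
  bool proper = false;
  bool recovered = false;
};

static std::string ops_to_cigar(const OpList& ops, bool emit_eqx) {
  std::string out;
  OpList merged;
  for (size_t i = 0; i < ops.op.size(); ++i) {
    char o = ops.op[i];
    if (!emit_eqx && (o == '=' || o == 'X')) o = 'M';
    merged.push(o, ops.len[i]);
  }
  for (size_t i = 0; i < merged.op.size(); ++i) {
    out += std::to_string(merged.len[i]);
    out += merged.op[i];
  }
  return out;
}

// single-end scoring of one mate given its candidates and chosen index
static MateRes score_mate(const std::vector<Cand>& cands, int chosen,
                          int read_len, const AlnCfg& cfg) {
  MateRes r;
  if (chosen < 0 || cands.empty()) return r;
  r.mapped = true;
  r.aln = cands[chosen];
  r.s1 = cands[chosen].score;
  r.s2 = 0;
  std::vector<double> others;
  for (size_t i = 0; i < cands.size(); ++i)
    if ((int)i != chosen) {
      others.push_back(cands[i].score);
      if (cands[i].score > r.s2) r.s2 = cands[i].score;
    }
  r.nsec = count_secondary_impl(others, r.s1, cfg.nsec_frac);
  r.mapq = mapq_single_impl(r.s1, r.s2, r.nsec, read_len, cfg.sc.m1, cfg.sc.m2);
  return r;
}

// attempt orphan recovery around an anchor alignment
static bool recover_orphan(const IndexView& v, const PGView& pg,
                           const LiftView& lf, const RefView& rf,
                           const AlnCfg& cfg, const MateRes& anchor,
                           const std::vector<uint8_t>& orphan_fwd,
                           double mu, double sigma, Cand* out) {
  int lo_ins = (int)std::floor(mu - 4.0 * sigma);
  int hi_ins = (int)std::ceil(mu + 4.0 * sigma);
  int m = (int)orphan_fwd.size();
  int doc = anchor.aln.doc;
  int dlen = pg.doc_len[doc];
  int a_start = anchor.aln.hap_start;
  int a_end = a_start + anchor.aln.hops.ref_len();
  int wlo, whi, ostrand;
  if (anchor.aln.strand == 0) { // anchor forward, mate expected downstream, rc
    wlo = a_start + std::max(0, lo_ins - m);
    whi = a_start + hi_ins;
    ostrand = 1;
  } else {
    wlo = a_end - hi_ins;
    whi = a_end - std::max(0, lo_ins - m);
    ostrand = 0;
  }
  wlo = std::max(0, wlo);
  whi = std::min(dlen, whi);
  if (whi - wlo < m / 2) return false;
  std::vector<uint8_t> oriented = ostrand == 0 ? orphan_fwd : revcomp(orphan_fwd);
  OpList ops;
  int b_start;
  int score = fit_align(oriented.data(), m, v.text + pg.doc_start[doc] + wlo,
                        whi - wlo, cfg.sc, &ops, &b_start);
  double floor_ = cfg.orphan_floor_frac * cfg.sc.m1 * m;
  if (score < floor_) return false;
  Cand cd;
  cd.doc = doc; cd.strand = ostrand;
  cd.hap_start = wlo + b_start;
  cd.score = score;
  cd.hops = ops;
  LiftSegs L = lf.segs(doc);
  OpList rops;
  int ref_start = -1;
  if (!lift_ops_impl(L, cd.hap_start, ops, &ref_start, &rops)) return false;
  cd.contig = lf.contig[doc];
  cd.rpos = ref_start;
  cd.rops = rops;
  cd.rspan = rops.ref_len();
  const uint8_t* ref = rf.contig_seq(cd.contig);
  const uint8_t* rd = oriented.data();
  int i = 0, j = ref_start, nm = 0, nx = 0;
  for (size_t k = 0; k < rops.op.size(); ++k) {
    char o = rops.op[k]; int L2 = rops.len[k];
    if (o == 'M' || o == '=' || o == 'X') {
      for (int t = 0; t < L2; ++t) if (!pm_match(rd[i + t], ref[j + t])) { ++nm; ++nx; }
      i += L2; j += L2;
    } else if (o == 'I') { nm += L2; i += L2; }
    else if (o == 'D') { nm += L2; j += L2; }
    else { i += L2; }
  }
  cd.nm = nm; cd.nx = nx;
  *out = cd;
  return true;
}

// [[Rcpp::export]]
List cpp_align_batch(List idx, List pg_list, List lift_list, List ref_list,
                     CharacterVector reads1, Nullable<CharacterVector> reads2_,
                     List cfg_list) {
  IndexView v(idx);
  PGView pg(pg_list);
  LiftView lf(lift_list);
  RefView rf(ref_list);
  AlnCfg cfg = cfg_from_list(cfg_list);
  bool paired = reads2_.isNotNull();
  CharacterVector reads2 = paired ? CharacterVector(reads2_) : CharacterVector(0);
  int npair = reads1.size();
  if (paired && reads2.size() != npair)
    stop("paired FASTQ files contain different read counts");

  // 1. candidate generation for every mate
  std::vector<std::vector<Cand>> C1(npair), C2(paired ? npair : 0);
  std::vector<std::vector<uint8_t>> R1(npair), R2(paired ? npair : 0);
  for (int i = 0; i < npair; ++i) {
    R1[i] = normalize_read(CHAR(STRING_ELT(reads1, i)));
    if (!R1[i].empty()) candidates_for_read(v, pg, lf, rf, cfg, R1[i], &C1[i]);
    if (paired) {
      R2[i] = normalize_read(CHAR(STRING_ELT(reads2, i)));
      if (!R2[i].empty()) candidates_for_read(v, pg, lf, rf, cfg, R2[i], &C2[i]);
    }
  }

  // 2. insert-size model from the first pairs whose mates align uniquely
  Welford model;
  if (paired) {
    for (int i = 0; i < npair && model.count < cfg.max_is_pairs; ++i) {
      auto uniq = [](const std::vector<Cand>& c) {
        return c.size() == 1 || (c.size() > 1 && c[0].score > c[1].score);
      };
      if (C1[i].empty() || C2[i].empty()) continue;
      if (!uniq(C1[i]) || !uniq(C2[i])) continue;
      const Cand& a = C1[i][0];
      const Cand& b = C2[i][0];
      if (a.contig != b.contig || a.strand == b.strand) continue;
      int outer = std::max(a.rpos + a.rspan, b.rpos + b.rspan) -
                  std::min(a.rpos, b.rpos);
      model.update((double)outer);
    }
  }
  bool model_ok = model.count >= 2;
  double mu = model.mean, sigma = model.sd();

  // 3. per-pair selection and SAM fields
  int nrec = paired ? 2 * npair : npair;
  IntegerVector o_qname(nrec), o_flag(nrec), o_rname(nrec), o_pos(nrec),
      o_mapq(nrec), o_rnext(nrec), o_pnext(nrec), o_tlen(nrec), o_nm(nrec);
  NumericVector o_as(nrec), o_xs(nrec);
  CharacterVector o_cigar(nrec);
  LogicalVector o_rev(nrec), o_mapped(nrec);

  for (int i = 0; i < npair; ++i) {
    MateRes m1, m2;
    bool proper = false;
    if (!paired) {
      m1 = score_mate(C1[i], C1[i].empty() ? -1 : 0, (int)R1[i].size(), cfg);
    } else {
      int bi = -1, bj = -1;
      double s1p = 0, s2p = 0;
      std::vector<double> pscores;
      if (!C1[i].empty() && !C2[i].empty())
        pair_select_impl(C1[i], C2[i], mu, sigma, model_ok, &bi, &bj,
                         &s1p, &s2p, &pscores);
      if (bi >= 0) {
        proper = true;
        m1 = score_mate(C1[i], bi, (int)R1[i].size(), cfg);
        m2 = score_mate(C2[i], bj, (int)R2[i].size(), cfg);
        // paired MAPQ (Eq. 3): Q' from Eq. 1 on paired scores
        int np = count_secondary_impl(pscores, s1p, cfg.nsec_frac);
        int lenp = (int)(R1[i].size() + R2[i].size());
        int Qp = mapq_single_impl(s1p, s2p, np, lenp, cfg.sc.m1, cfg.sc.m2);
        m1.mapq = mapq_paired_impl(m1.mapq, Qp, s1p, s2p, cfg.sc.m1);
        m2.mapq = mapq_paired_impl(m2.mapq, Qp, s1p, s2p, cfg.sc.m1);
        m1.proper = m2.proper = true;
      } else {
        // no window-compatible combination: best-per-mate, orphan recovery
        m1 = score_mate(C1[i], C1[i].empty() ? -1 : 0, (int)R1[i].size(), cfg);
        m2 = score_mate(C2[i], C2[i].empty() ? -1 : 0, (int)R2[i].size(), cfg);
        if (cfg.orphan_on && model_ok && (m1.mapped != m2.mapped)) {
          const MateRes& anchor = m1.mapped ? m1 : m2;
          const std::vector<uint8_t>& oseq = m1.mapped ? R2[i] : R1[i];
          Cand rec;
          if (!oseq.empty() &&
              recover_orphan(v, pg, lf, rf, cfg, anchor, oseq, mu, sigma, &rec)) {
            MateRes mr;
            mr.mapped = true;
            mr.aln = rec;
            mr.s1 = rec.score; mr.s2 = 0; mr.nsec = 0;
            mr.mapq = mapq_single_impl(rec.score, 0, 0, (int)oseq.size(),
                                       cfg.sc.m1, cfg.sc.m2);
            mr.recovered = true;
            mr.proper = true;
            if (m1.mapped) { m2 = mr; m1.proper = true; }
            else { m1 = mr; m2.proper = true; }
            proper = true;
          }
        }
      }
    }

    // emit records
    auto emit = [&](int slot, const MateRes& me, const MateRes& other,
                    int which, int rlen) {
      int flag = 0;
      if (paired) {
        flag |= 0x1 | (which == 1 ? 0x40 : 0x80);
        if (!other.mapped) flag |= 0x8;
        if (other.mapped && other.aln.strand == 1) flag |= 0x20;
        if (me.proper && me.mapped && other.mapped) flag |= 0x2;
      }
      if (!me.mapped) {
        flag |= 0x4;
        o_qname[slot] = i + 1; o_flag[slot] = flag;
        o_rname[slot] = -1; o_pos[slot] = -1; o_mapq[slot] = 0;
        o_cigar[slot] = "*"; o_rnext[slot] = -1; o_pnext[slot] = -1;
        o_tlen[slot] = 0; o_as[slot] = NA_REAL; o_xs[slot] = NA_REAL;
        o_nm[slot] = NA_INTEGER; o_rev[slot] = false; o_mapped[slot] = false;
        return;
      }
      if (me.aln.strand == 1) flag |= 0x10;
      o_qname[slot] = i + 1;
      o_flag[slot] = flag;
      o_rname[slot] = me.aln.contig;
      o_pos[slot] = me.aln.rpos;
      o_mapq[slot] = me.mapq;
      o_cigar[slot] = ops_to_cigar(me.aln.rops, cfg.emit_eqx);
      o_as[slot] = me.aln.score;
      o_xs[slot] = me.s2 > 0 ? me.s2 : NA_REAL;
      o_nm[slot] = me.aln.nm;
      o_rev[slot] = me.aln.strand == 1;
      o_mapped[slot] = true;
      if (paired && other.mapped) {
        o_rnext[slot] = other.aln.contig == me.aln.contig ? -2 : other.aln.contig;
        o_pnext[slot] = other.aln.rpos;
        if (other.aln.contig == me.aln.contig) {
          int a0 = me.aln.rpos, a1 = me.aln.rpos + me.aln.rspan;
          int b0 = other.aln.rpos, b1 = other.aln.rpos + other.aln.rspan;
          int outer = std::max(a1, b1) - std::min(a0, b0);
          int sign;
          if (a0 < b0) sign = 1;
          else if (a0 > b0) sign = -1;
          else sign = which == 1 ? 1 : -1;
          o_tlen[slot] = sign * outer;
        } else o_tlen[slot] = 0;
      } else {
        o_rnext[slot] = -1; o_pnext[slot] = -1; o_tlen[slot] = 0;
      }
    };

    if (!paired) {
      emit(i, m1, MateRes(), 1, (int)R1[i].size());
    } else {
      emit(2 * i, m1, m2, 1, (int)R1[i].size());
      emit(2 * i + 1, m2, m1, 2, (int)R2[i].size());
    }
  }

  return List::create(
      _["qname"] = o_qname, _["flag"] = o_flag, _["rname"] = o_rname,
      _["pos"] = o_pos, _["mapq"] = o_mapq, _["cigar"] = o_cigar,
      _["rnext"] = o_rnext, _["pnext"] = o_pnext, _["tlen"] = o_tlen,
      _["as"] = o_as, _["xs"] = o_xs, _["nm"] = o_nm, _["rev"] = o_rev,
      _["mapped"] = o_mapped,
      _["insert_count"] = (double)model.count,
      _["insert_mean"] = model.mean, _["insert_sd"] = model.sd());
}

// Seed diagnostics for one read: used by the R-level seeding surface and the
// MEM statistics CSV.  Returns per-seed rows after cap, plus filter stages.
// [[Rcpp::export]]
List cpp_read_seeds(List idx, List pg_list, CharacterVector read, List cfg_list) {
  IndexView v(idx);
  PGView pg(pg_list);
  AlnCfg cfg = cfg_from_list(cfg_list);
  std::vector<uint8_t> fwd = normalize_read(CHAR(STRING_ELT(read, 0)));
  std::vector<SeedS> seeds;
  if (!fwd.empty()) gen_seeds(v, pg, cfg, fwd, &seeds);
  int k = (int)seeds.size();
  IntegerVector x(k), len(k), strand(k), nocc(k);
  NumericVector total(k);
  List occs(k);
  for (int i = 0; i < k; ++i) {
    x[i] = seeds[i].x + 1;
    len[i] = seeds[i].len;
    strand[i] = seeds[i].strand;
    nocc[i] = (int)seeds[i].occ.size();
    total[i] = (double)seeds[i].total_uncapped;
    IntegerMatrix om(seeds[i].occ.size(), 2);
    for (size_t j = 0; j < seeds[i].occ.size(); ++j) {
      om(j, 0) = seeds[i].occ[j].first + 1;
      om(j, 1) = seeds[i].occ[j].second + 1;
    }
    occs[i] = om;
  }
  return List::create(_["start"] = x, _["len"] = len, _["strand"] = strand,
                      _["n_occ"] = nocc, _["total_uncapped"] = total,
                      _["occ"] = occs);
}
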