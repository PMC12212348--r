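#include "panmem.h"
using namespace Rcpp;

// Karp-Rabin hash used to pick trigger strings: polynomial hash of the byte
// values with base PM_KR_BASE modulo the 61-bit Mersenne prime, reduced
// modulo the user's p.  A window is a trigger iff its reduced hash is 0 or
// the window consists solely of the delimiter byte.
static const uint64_t PM_KR_MOD = (1ULL << 61) - 1;
static const uint64_t PM_KR_BASE = 1000000007ULL;

static inline uint64_t mulmod61(uint64_t a, uint64_t b) {
  __uint128_t z = ( __uint128_t )a * b;
  uint64_t lo = (uint64_t)(z & PM_KR_MOD);
  uint64_t hi = (uint64_t)(z >> 61);
  uint64_t s = lo + hi;
  if (s >= PM_KR_MOD) s -= PM_KR_MOD;
  return s;
}
static inline uint64_t addmod61(uint64_t a, uint64_t b) {
  uint64_t s = a + b;
  if (s >= PM_KR_MOD) s -= PM_KR_MOD;
  return s;
}

// Direct (non-rolling) evaluation of the window hash reduced mod p; serves
// as an independent per-window evaluation for the full-scan oracle.
// [[Rcpp::export]]
int cpp_pfp_window_hash_modp(RawVector window, double p) {
  uint64_t h = 0;
  for (int i = 0; i < window.size(); ++i)
    h = addmod61(mulmod61(h, PM_KR_BASE), (uint64_t)window[i]);
  return (int)(h % (uint64_t)p);
}

// All trigger occurrence positions (0-based) in the delimited text sprime.
// With explicit_triggers given, occurrences of those strings are reported
// instead of hash-selected ones (the delimiter window is always a trigger).
// [[Rcpp::export]]
IntegerVector cpp_pfp_triggers(RawVector sprime, int w, double p,
                               Nullable<List> explicit_triggers, RawVector delim) {
  int n = sprime.size();
  if (w < 2) stop("w must be >= 2");
  if (n < w) stop("text shorter than the window length");
  const uint8_t* s = RAW(sprime);
  uint8_t d = delim[0];
  std::vector<int> out;

  if (explicit_triggers.isNotNull()) {
    List trig(explicit_triggers);
    std::vector<const uint8_t*> ts;
    for (int k = 0; k < trig.size(); ++k) {
      RawVector t = trig[k];
      if (t.size() != w) stop("explicit trigger strings must have length w");
      ts.push_back(RAW(t));
    }
    for (int i = 0; i + w <= n; ++i) {
      bool hit = true;
      for (int j = 0; j < w; ++j) if (s[i + j] != d) { hit = false; break; }
      if (!hit) {
        for (size_t k = 0; k < ts.size() && !hit; ++k) {
          hit = true;
          for (int j = 0; j < w; ++j)
            if (s[i + j] != ts[k][j]) { hit = false; break; }
        }
      }
      if (hit) out.push_back(i);
    }
    return IntegerVector(out.begin(), out.end());
  }

  if (p < 1) stop("p must be >= 1");
  uint64_t pp = (uint64_t)p;
  // rolling hash
  uint64_t bw = 1; // BASE^(w-1)
  for (int i = 0; i < w - 1; ++i) bw = mulmod61(bw, PM_KR_BASE);
  uint64_t h = 0;
  int dcount = 0;
  for (int i = 0; i < w; ++i) {
    h = addmod61(mulmod61(h, PM_KR_BASE), (uint64_t)s[i]);
    if (s[i] == d) ++dcount;
  }
  for (int i = 0; i + w <= n; ++i) {
    if (i > 0) {
      uint64_t drop = mulmod61(bw, (uint64_t)s[i - 1]);
      h = addmod61(h, PM_KR_MOD - drop);
      h = addmod61(mulmod61(h, PM_KR_BASE), (uint64_t)s[i + w - 1]);
      if (s[i - 1] == d) --dcount;
      if (s[i + w - 1] == d) ++dcount;
    }
    if (h % pp == 0 || dcount == w) out.push_back(i);
  }
  return IntegerVector(out.begin(), out.end());
}
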