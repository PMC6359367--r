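#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Banded Levenshtein distance with cutoff. Returns the exact distance when it
// is <= cutoff, and cutoff + 1 otherwise. Cells outside the |i - j| <= cutoff
// band cannot lie on a path of cost <= cutoff, so the band plus a row-minimum
// early exit never changes results, only work.
static int lev_bounded(const std::string &sa, const std::string &sb, int cutoff) {
  const std::string *pa = &sa, *pb = &sb;
  if (pa->size() > pb->size()) std::swap(pa, pb);
  const std::string &a = *pa, &b = *pb;
  const int la = (int)a.size(), lb = (int)b.size();
  if (lb - la > cutoff) return cutoff + 1;
  const int INF = cutoff + 1;
  std::vector<int> d(la + 1);
  for (int j = 0; j <= la; ++j) d[j] = (j <= cutoff) ? j : INF;
  for (int i = 1; i <= lb; ++i) {
    const int lo = std::max(1, i - cutoff);
    const int hi = std::min(la, i + cutoff);
    int prev_diag = d[lo - 1];                  // row i-1, col lo-1
    int left = (lo == 1) ? ((i <= cutoff) ? i : INF) : INF;
    d[lo - 1] = left;                           // row i, col lo-1 (for next row's diag)
    int best = INF;
    for (int j = lo; j <= hi; ++j) {
      const int up = (j <= i - 1 + cutoff) ? d[j] : INF;
      const int cost = (a[j - 1] == b[i - 1]) ? 0 : 1;
      int cur = prev_diag + cost;
      if (up + 1 < cur) cur = up + 1;
      if (left + 1 < cur) cur = left + 1;
      if (cur > INF) cur = INF;
      prev_diag = d[j];
      d[j] = cur;
      left = cur;
      if (cur < best) best = cur;
    }
    if (best > cutoff) return cutoff + 1;
  }
  return (d[la] <= cutoff) ? d[la] : cutoff + 1;
}

//' @noRd
// [[Rcpp::export(name = ".lev_dist_cpp")]]
IntegerVector lev_dist_cpp(CharacterVector a, CharacterVector b, int cutoff = -1) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("'a' and 'b' must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const std::string sa = as<std::string>(a[i]);
    const std::string sb = as<std::string>(b[i]);
    int cut = cutoff;
    if (cut < 0) cut = (int)std::max(sa.size(), sb.size());
    out[i] = lev_bounded(sa, sb, cut);
  }
  return out;
}

// q-gram lemma (q = 4): a single edit changes at most q of a string's
// q-grams, so LD >= L1(profile_a, profile_b) / (2q). The profile screen is a
// pure lower bound: it only skips pairs whose distance provably exceeds t.
static const int QG = 4;

static bool qgram_profile(const std::string &s, uint16_t *prof) {
  std::fill(prof, prof + 256, 0);
  const int n = (int)s.size();
  if (n < QG) return false;
  int code = 0;
  int run = 0;  // valid consecutive bases
  for (int i = 0; i < n; ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: return false;  // ambiguous base: no screening for this string
    }
    code = ((code << 2) | b) & 0xFF;
    if (++run >= QG && prof[code] < 65535) ++prof[code];
  }
  return true;
}

static inline bool qgram_within(const uint16_t *pa, const uint16_t *pb, int lim) {
  int l1 = 0;
  for (int k = 0; k < 256; ++k) {
    l1 += pa[k] > pb[k] ? pa[k] - pb[k] : pb[k] - pa[k];
    if (l1 > lim) return false;
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".lev_pairs_cpp")]]
DataFrame lev_pairs_cpp(CharacterVector seqs, int t) {
  const int n = (int)seqs.size();
  std::vector<std::string> s(n);
  std::vector<int> len(n);
  std::vector<uint16_t> prof((size_t)n * 256);
  std::vector<char> screened(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    len[i] = (int)s[i].size();
    screened[i] = qgram_profile(s[i], &prof[(size_t)i * 256]) ? 1 : 0;
  }
  const int qlim = 2 * QG * t;
  // bucket by length: only pairs with |len_i - len_j| <= t are candidates
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int x, int y) { return len[x] < len[y]; });
  std::vector<int> va, vb, vd;
  for (int ii = 0; ii < n; ++ii) {
    const int i = ord[ii];
    for (int jj = ii + 1; jj < n; ++jj) {
      const int j = ord[jj];
      if (len[j] - len[i] > t) break;  // sorted: no further candidate
      if (screened[i] && screened[j] &&
          !qgram_within(&prof[(size_t)i * 256], &prof[(size_t)j * 256], qlim))
        continue;
      const int d = lev_bounded(s[i], s[j], t);
      if (d >= 1 && d <= t) {
        int p = i, q = j;
        if (p > q) std::swap(p, q);
        va.push_back(p + 1);
        vb.push_back(q + 1);
        vd.push_back(d);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["a"] = wrap(va), _["b"] = wrap(vb), _["ld"] = wrap(vd));
}

// Sliding Hamming search for a primer near one read end. Returns the 0-based
// start offset of the best (fewest mismatches, then closest to the end) match
// with <= max_mm mismatches, or -1.
static int hamming_locate(const std::string &seq, const std::string &pat,
                          int max_mm, int window, bool from_end) {
  const int ls = (int)seq.size(), lp = (int)pat.size();
  if (lp > ls) return -1;
  int best_pos = -1, best_mm = max_mm + 1;
  for (int k = 0; k < window; ++k) {
    const int pos = from_end ? (ls - lp - k) : k;
    if (pos < 0) break;
    int mm = 0;
    for (int j = 0; j < lp && mm < best_mm; ++j)
      if (seq[pos + j] != pat[j]) ++mm;
    if (mm < best_mm) { best_mm = mm; best_pos = pos; }
    if (best_mm == 0) break;
  }
  return (best_mm <= max_mm) ? best_pos : -1;
}

//' @noRd
// [[Rcpp::export(name = ".primer_hits_cpp")]]
IntegerMatrix primer_hits_cpp(CharacterVector seqs, std::string fwd,
                              std::string rev_rc, int max_mm, int window) {
  const R_xlen_t n = seqs.size();
  IntegerMatrix out(n, 2);  // col 0: fwd start (0-based), col 1: rev_rc start
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    out(i, 0) = hamming_locate(s, fwd, max_mm, window, false);
    out(i, 1) = hamming_locate(s, rev_rc, max_mm, window, true);
  }
  return out;
}
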