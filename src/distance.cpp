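#include <Rcpp.h>
#include <climits>
#include <cstdlib>
#include <string>
#include <vector>
using namespace Rcpp;

// Sentinel well below overflow when incremented.
static const int NOVAL = INT_MAX / 4;

// Banded Levenshtein DP restricted to |i - j| <= k.  With end_tol the
// trailing overhang of either sequence is free: the answer is
// min( min_j D[n][j], min_i D[i][m] ) instead of D[n][m].  Any cell
// (i, m) or (n, j) holding a value <= k lies inside the band because a
// cell's value is always >= |i - j|, so the band is exact, not a
// heuristic.  Rows whose in-band minimum exceeds k can never improve a
// later cell (every path to a later cell crosses the current row), so
// the scan exits early.
static int band_dp(const std::string& a, const std::string& b, int k,
                   bool end_tol, bool& exceeded) {
  const int n = (int) a.size(), m = (int) b.size();
  exceeded = false;
  if (k < 0) { exceeded = true; return 0; }
  if (!end_tol && std::abs(n - m) > k) { exceeded = true; return 0; }
  if (n == 0 || m == 0) {
    int v = end_tol ? 0 : (n == 0 ? m : n);
    exceeded = v > k;
    return exceeded ? 0 : v;
  }
  std::vector<int> prev((size_t) m + 1, NOVAL), cur((size_t) m + 1, NOVAL);
  int best_tail = NOVAL;  // min over column-m cells seen so far
  const int hi0 = std::min(m, k);
  for (int j = 0; j <= hi0; ++j) prev[j] = j;
  if (end_tol && m <= k) best_tail = prev[m];
  for (int i = 1; i <= n; ++i) {
    const int lo = std::max(0, i - k), hi = std::min(m, i + k);
    if (lo > m) break;  // band has run past the end of b
    std::fill(cur.begin(), cur.end(), NOVAL);
    int rowmin = NOVAL;
    for (int j = lo; j <= hi; ++j) {
      int best = NOVAL;
      if (j == 0) {
        best = i;  // i deletions; in band only when i <= k
      } else {
        if (prev[j - 1] < NOVAL) {
          int c = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (c < best) best = c;
        }
        if (prev[j] < NOVAL && prev[j] + 1 < best) best = prev[j] + 1;
        if (cur[j - 1] < NOVAL && cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      }
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (end_tol && hi == m && cur[m] < best_tail) best_tail = cur[m];
    if (i == n) {
      int ans;
      if (end_tol) {
        ans = best_tail;
        for (int j = lo; j <= hi; ++j)
          if (cur[j] < ans) ans = cur[j];
      } else {
        ans = cur[m];
      }
      exceeded = ans > k;
      return exceeded ? 0 : ans;
    }
    if (rowmin > k) {
      if (end_tol && best_tail <= k) return best_tail;
      exceeded = true;
      return 0;
    }
    std::swap(prev, cur);
  }
  if (end_tol && best_tail <= k) return best_tail;
  exceeded = true;
  return 0;
}

// [[Rcpp::export]]
List dist_bounded_cpp(std::string a, std::string b, int k, bool end_tolerant) {
  bool exceeded = false;
  int v = band_dp(a, b, k, end_tolerant, exceeded);
  return List::create(_["value"] = exceeded ? NA_INTEGER : v,
                      _["exceeded"] = exceeded,
                      _["bound"] = k);
}

// Cumulative forward+reverse distance of many read pairs against one
// reference pair, bounded by k over the pair.  NA when the bound is
// exceeded.  Reverse strings may be empty (single-read mode).
// [[Rcpp::export]]
IntegerVector pair_dist_cpp(CharacterVector fwd, CharacterVector rev,
                            std::string ref_fwd, std::string ref_rev,
                            int k, bool end_tolerant) {
  const R_xlen_t n = fwd.size();
  if (rev.size() != n) stop("fwd and rev must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (fwd[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    bool exc = false;
    std::string f = as<std::string>(fwd[i]);
    int d1 = band_dp(f, ref_fwd, k, end_tolerant, exc);
    if (exc) { out[i] = NA_INTEGER; continue; }
    std::string r = (rev[i] == NA_STRING) ? std::string()
                                          : as<std::string>(rev[i]);
    int d2 = band_dp(r, ref_rev, k - d1, end_tolerant, exc);
    out[i] = exc ? NA_INTEGER : d1 + d2;
  }
  return out;
}
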