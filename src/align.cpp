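#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Exact unit-cost Levenshtein distance via band doubling (Ukkonen).
// A band of half-width h yields the exact distance whenever the true
// distance is <= h, so we double h until the computed value fits the band.
static int banded_levenshtein(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  int diff = std::abs(n - m);
  int h = diff + 8;
  const int INF = INT_MAX / 4;
  for (;;) {
    if (h >= n + m) h = n + m;
    std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
    for (int j = 0; j <= std::min(m, h); ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
      int lo = std::max(1, i - h), hi = std::min(m, i + h);
      std::fill(cur.begin(), cur.end(), INF);
      if (lo == 1) cur[0] = i;
      for (int j = lo; j <= hi; ++j) {
        int best = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
        if (prev[j] + 1 < best) best = prev[j] + 1;
        if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
        cur[j] = best;
      }
      std::swap(prev, cur);
    }
    int d = prev[m];
    if (d <= h || h >= n + m) return d;
    h *= 2;
  }
}

// [[Rcpp::export(name = ".cpp_edit_distance")]]
int cpp_edit_distance(std::string a, std::string b) {
  return banded_levenshtein(a, b);
}

// [[Rcpp::export(name = ".cpp_edit_distance_matrix")]]
IntegerMatrix cpp_edit_distance_matrix(CharacterVector a, CharacterVector b) {
  IntegerMatrix out(a.size(), b.size());
  std::vector<std::string> bs(b.size());
  for (int j = 0; j < b.size(); ++j) bs[j] = as<std::string>(b[j]);
  for (int i = 0; i < a.size(); ++i) {
    std::string ai = as<std::string>(a[i]);
    for (int j = 0; j < b.size(); ++j) out(i, j) = banded_levenshtein(ai, bs[j]);
  }
  return out;
}

// Global unit-cost alignment of a (reference/draft segment) against b
// (read segment), returning the edit cost and the monotone boundary map
// cuts[i] = number of b characters consumed after the first i characters
// of a (length n+1, cuts[0] = 0 only when the path has no leading
// insertions; insertions at row i are charged before boundary i).
// Traceback prefers diagonal, then a-gap (deletion), then b-gap.
// [[Rcpp::export(name = ".cpp_nw_cuts")]]
List cpp_nw_cuts(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback: 0 = diag, 1 = up (consume a), 2 = left (consume b)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  for (int j = 0; j <= m; ++j) { prev[j] = j; if (j > 0) tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int dg = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      int lf = cur[j - 1] + 1;
      int best = dg; unsigned char op = 0;
      if (up < best) { best = up; op = 1; }
      if (lf < best) { best = lf; op = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = op;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  IntegerVector cuts(n + 1);
  int i = n, j = m;
  cuts[n] = m;
  while (i > 0 || j > 0) {
    unsigned char op = tb[(size_t)i * (m + 1) + j];
    if (op == 0)      { --i; --j; cuts[i] = j; }
    else if (op == 1) { --i;      cuts[i] = j; }
    else              { --j; }
  }
  return List::create(_["score"] = score, _["cuts"] = cuts);
}
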