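#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Longest strictly increasing subsequence of `values`; returns 1-based
// indices of one optimal subsequence (patience sorting with parent
// pointers, ties resolved identically to the reference R implementation).
// [[Rcpp::export(.cpp_lis_indices)]]
IntegerVector cpp_lis_indices(NumericVector values) {
  int n = values.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> tails;
  std::vector<int> tail_idx;
  std::vector<int> parent(n, -1);
  tails.reserve(n);
  tail_idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    double v = values[i];
    // first tail >= v (strictly increasing subsequence)
    size_t j = std::lower_bound(tails.begin(), tails.end(), v) - tails.begin();
    if (j == tails.size()) {
      tails.push_back(v);
      tail_idx.push_back(i);
    } else {
      tails[j] = v;
      tail_idx[j] = i;
    }
    parent[i] = (j > 0) ? tail_idx[j - 1] : -1;
  }
  int len = tails.size();
  IntegerVector out(len);
  int cur = tail_idx[len - 1];
  for (int s = len - 1; s >= 0; --s) {
    out[s] = cur + 1;
    cur = parent[cur];
  }
  return out;
}

// Merge chained seed anchors into maximal same-diagonal blocks.
// Anchors are 1-based start positions of length-`sk` exact matches in the
// draft (anchors_d) and read (anchors_r), already chained so both
// coordinates are strictly increasing. Consecutive anchors on the same
// diagonal whose spans touch or overlap are extended into one block;
// anchors overlapping the previous block from a different diagonal are
// dropped. Returns a matrix with columns ds, de, rs, re (1-based,
// inclusive).
// [[Rcpp::export(.cpp_merge_anchor_blocks)]]
IntegerMatrix cpp_merge_anchor_blocks(IntegerVector anchors_d,
                                      IntegerVector anchors_r, int sk) {
  int n = anchors_d.size();
  std::vector<int> ds, de, rs, re;
  ds.reserve(n); de.reserve(n); rs.reserve(n); re.reserve(n);
  for (int a = 0; a < n; ++a) {
    int dp = anchors_d[a], rp = anchors_r[a];
    if (!ds.empty()) {
      size_t m = ds.size() - 1;
      bool same_diag = (rp - dp) == (rs[m] - ds[m]);
      if (dp <= de[m] || rp <= re[m]) {
        if (same_diag && dp > ds[m]) {
          de[m] = dp + sk - 1;
          re[m] = rp + sk - 1;
        }
        continue;
      }
    }
    ds.push_back(dp); de.push_back(dp + sk - 1);
    rs.push_back(rp); re.push_back(rp + sk - 1);
  }
  int m = ds.size();
  IntegerMatrix out(m, 4);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = ds[i]; out(i, 1) = de[i];
    out(i, 2) = rs[i]; out(i, 3) = re[i];
  }
  colnames(out) = CharacterVector::create("ds", "de", "rs", "re");
  return out;
}
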