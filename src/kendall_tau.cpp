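#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

// Kendall tau-b in O(n log n) (Knight's algorithm): sort by (x, y), count
// discordant pairs as strict inversions of the y sequence with a merge
// sort, and correct the denominator for ties in each margin.

static int64_t merge_count(std::vector<double>& v, std::vector<double>& buf,
                           size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  int64_t cnt = merge_count(v, buf, lo, mid) + merge_count(v, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (v[j] < v[i]) {            // strict inversion only
      cnt += (int64_t)(mid - i);
      buf[k++] = v[j++];
    } else {
      buf[k++] = v[i++];
    }
  }
  while (i < mid) buf[k++] = v[i++];
  while (j < hi)  buf[k++] = v[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
  return cnt;
}

static int64_t tie_pairs(const std::vector<double>& sorted) {
  int64_t t = 0, run = 1;
  for (size_t i = 1; i <= sorted.size(); ++i) {
    if (i < sorted.size() && sorted[i] == sorted[i - 1]) {
      ++run;
    } else {
      t += run * (run - 1) / 2;
      run = 1;
    }
  }
  return t;
}

// [[Rcpp::export]]
double kendall_tau_b_cpp(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  const size_t n = x.size();
  if (y.size() != (R_xlen_t)n) Rcpp::stop("x and y must have equal length");
  if (n < 2) Rcpp::stop("need at least 2 observations");

  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> ys(n);
  for (size_t i = 0; i < n; ++i) ys[i] = y[ord[i]];

  const int64_t n0 = (int64_t)n * (int64_t)(n - 1) / 2;

  // ties in x, and joint ties, from the sorted order
  int64_t n1 = 0, n3 = 0;
  {
    int64_t run_x = 1;
    size_t start = 0;
    for (size_t i = 1; i <= n; ++i) {
      if (i < n && x[ord[i]] == x[ord[i - 1]]) {
        ++run_x;
      } else {
        n1 += run_x * (run_x - 1) / 2;
        std::vector<double> grp(ys.begin() + start, ys.begin() + i);
        n3 += tie_pairs(grp);   // y ties within an x-tie group = joint ties
        run_x = 1;
        start = i;
      }
    }
  }

  std::vector<double> buf(n);
  const int64_t nd = merge_count(ys, buf, 0, n);   // ys now sorted
  const int64_t n2 = tie_pairs(ys);

  const double nc = (double)(n0 - n1 - n2 + n3 - nd);
  const double denom = std::sqrt((double)(n0 - n1)) * std::sqrt((double)(n0 - n2));
  if (denom <= 0) Rcpp::stop("tau-b undefined: a margin has zero variance");
  return (nc - (double)nd) / denom;
}
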