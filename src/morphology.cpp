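#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3-D logical array (column-major,
// dims = c(n1, n2, n3)). Labels are assigned in scan order of the first
// foreground voxel of each component; 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next_label;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % n1);
      int j = (int)((v / n1) % n2);
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di;
            if (ii < 0 || ii >= n1) continue;
            R_xlen_t w = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
            if (mask[w] && !labels[w]) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Binary dilation by a Chebyshev ball of radius r (r iterations of
// 26-neighbour dilation).
// [[Rcpp::export(name = ".dilate_cpp")]]
LogicalVector dilate_cpp(LogicalVector mask, IntegerVector dims, int r) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<char> cur(mask.begin(), mask.end());
  std::vector<char> nxt(n);
  for (int it = 0; it < r; ++it) {
    std::copy(cur.begin(), cur.end(), nxt.begin());
    for (R_xlen_t v = 0; v < n; ++v) {
      if (!cur[v]) continue;
      int i = (int)(v % n1);
      int j = (int)((v / n1) % n2);
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= n1) continue;
            nxt[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)] = 1;
          }
        }
      }
    }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  return out;
}
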