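// 3D connected-component labeling under 26-connectivity (BFS, deterministic
// scan order). Returns raw first-encounter labels; relabeling by component
// size happens on the R side.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label26(const IntegerVector& mask, const IntegerVector& dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (mask[v] == 0 || lab[v] != 0) continue;
    ++next;
    lab[v] = next;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = cur % n1;
      const int j = (cur / n1) % n2;
      const int k = cur / ((R_xlen_t)n1 * n2);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= n1) continue;
            const R_xlen_t w = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
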