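#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labelling of a 3-D logical mask.
// Labels are assigned in first-encounter scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  long sy = nx, sz = (long)nx * ny;
  int next = 0;
  std::vector<long> stack;
  for (long c0 = 0; c0 < n; ++c0) {
    if (!mask[c0] || lab[c0] != 0) continue;
    ++next;
    lab[c0] = next;
    stack.push_back(c0);
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      int i = (int)(c % nx);
      int j = (int)((c / nx) % ny);
      int k = (int)(c / sz);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            long cc = ii + (long)jj * sy + (long)kk * sz;
            if (mask[cc] && lab[cc] == 0) {
              lab[cc] = next;
              stack.push_back(cc);
            }
          }
    }
  }
  lab.attr("dim") = d;
  return lab;
}
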