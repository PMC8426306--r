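#include <Rcpp.h>
#include <vector>

// 6-connected component labelling of a 3D logical mask by iterative
// flood fill. Returns an integer vector of labels (0 = background) with
// attribute "n" giving the number of components.
// [[Rcpp::export]]
Rcpp::IntegerVector cc_label3d(Rcpp::LogicalVector mask, Rcpp::IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");
  Rcpp::IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / sz);
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {x > 0, x < nx - 1, y > 0, y < ny - 1, z > 0, z < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (!ok[k]) continue;
        R_xlen_t w = nb[k];
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
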