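#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 6-connected component labelling of a 3-D logical mask by BFS flood fill.
// Returns an integer array of the same shape: 0 outside the mask, components
// labelled 1..k in first-encounter order.
// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx * ny * nz != mask.size()) stop("mask size does not match dims");

  IntegerVector labels(mask.size(), 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;
  const R_xlen_t sx = 1, sy = nx, sz = nx * ny;

  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (mask[start] != TRUE || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      R_xlen_t z = v / sz, rem = v % sz, y = rem / sy, x = rem % sy;
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {x > 0, x < nx - 1, y > 0, y < ny - 1,
                          z > 0, z < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (!ok[k]) continue;
        R_xlen_t u = nb[k];
        if (mask[u] == TRUE && labels[u] == 0) {
          labels[u] = next_label;
          queue.push_back(u);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = next_label;
  return labels;
}
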