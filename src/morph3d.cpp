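#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Volumes are R arrays with dim = (n1, n2, n3), column-major:
// linear index = i1 + n1 * (i2 + n2 * i3), all 0-based here.

// Separable box mean along one axis with truncated windows at the borders
// (each output voxel is the mean of the in-volume voxels of its window).
static void box_mean_axis(std::vector<double> &v, int n1, int n2, int n3,
                          int axis, int half) {
  int n[3] = {n1, n2, n3};
  int stride[3] = {1, n1, n1 * n2};
  int len = n[axis], st = stride[axis];
  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  std::vector<double> line(len);
  for (int b = 0; b < n[o2]; ++b) {
    for (int a = 0; a < n[o1]; ++a) {
      int base = a * stride[o1] + b * stride[o2];
      double run = 0.0;
      // prefix sums via running window
      for (int i = 0; i < len; ++i) line[i] = v[base + i * st];
      for (int i = 0; i < len; ++i) {
        int lo = i - half, hi = i + half;
        if (lo < 0) lo = 0;
        if (hi > len - 1) hi = len - 1;
        if (i == 0) {
          run = 0.0;
          for (int j = lo; j <= hi; ++j) run += line[j];
        } else {
          int plo = i - 1 - half, phi = i - 1 + half;
          if (plo < 0) plo = 0;
          if (phi > len - 1) phi = len - 1;
          if (lo > plo) run -= line[plo];
          if (hi > phi) run += line[hi];
        }
        v[base + i * st] = run / double(hi - lo + 1);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_mean3(NumericVector vol, IntegerVector dim, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel edge must be a positive odd integer");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  int half = (k - 1) / 2;
  if (half > 0) {
    box_mean_axis(v, n1, n2, n3, 0, half);
    box_mean_axis(v, n1, n2, n3, 1, half);
    box_mean_axis(v, n1, n2, n3, 2, half);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling (6- or 26-connectivity), BFS, labels 1..K
// in first-encounter (linear scan) order, so labeling is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim,
                         int connectivity) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<int> off1, off2, off3;
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        int m = std::abs(d1) + std::abs(d2) + std::abs(d3);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        off1.push_back(d1); off2.push_back(d2); off3.push_back(d3);
      }
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i3 = cur / ((R_xlen_t)n1 * n2);
      int rem = cur - (R_xlen_t)i3 * n1 * n2;
      int i2 = rem / n1, i1 = rem - i2 * n1;
      for (size_t j = 0; j < off1.size(); ++j) {
        int a = i1 + off1[j], b = i2 + off2[j], c = i3 + off3[j];
        if (a < 0 || a >= n1 || b < 0 || b >= n2 || c < 0 || c >= n3) continue;
        R_xlen_t nb = a + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          q.push(nb);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Binary dilation by an arbitrary structuring element given as a matrix of
// integer voxel offsets (rows: offsets, cols: the three axes).
// [[Rcpp::export]]
LogicalVector cpp_dilate3(LogicalVector mask, IntegerVector dim,
                          IntegerMatrix offsets) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n, false);
  int m = offsets.nrow();
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i3 = s / ((R_xlen_t)n1 * n2);
    int rem = s - (R_xlen_t)i3 * n1 * n2;
    int i2 = rem / n1, i1 = rem - i2 * n1;
    for (int j = 0; j < m; ++j) {
      int a = i1 + offsets(j, 0), b = i2 + offsets(j, 1), c = i3 + offsets(j, 2);
      if (a < 0 || a >= n1 || b < 0 || b >= n2 || c < 0 || c >= n3) continue;
      out[a + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c)] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}
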