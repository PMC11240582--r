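#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope-of-parabolas algorithm, anisotropic spacing.
// INF_VAL stands in for +infinity so the parabola arithmetic stays finite.
static const double INF_VAL = 1e30;

// One 1-D pass: f holds squared distances at samples spaced h apart;
// d receives the lower envelope evaluated at the samples.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, double h) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF_VAL;
  z[1] = INF_VAL;
  for (int q = 1; q < n; q++) {
    double s = 0.0;
    for (;;) {
      const int vk = v[k];
      const double qh = q * h, vh = vk * h;
      s = ((f[q] + qh * qh) - (f[vk] + vh * vh)) / (2.0 * (qh - vh));
      if (s <= z[k] && k > 0) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF_VAL;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    const double x = q * h;
    while (z[k + 1] < x) k++;
    const double dx = x - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of `mask`, a column-major array with dimensions `dims` (up to 3)
// and physical sample spacing `spacing` (same order as dims).
// Voxels with no TRUE voxel anywhere come back as +Inf.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nd = dims.size();
  if (nd < 1 || nd > 3) stop("dims must have length 1, 2 or 3");
  if (spacing.size() != nd) stop("spacing length must match dims");
  int d1 = dims[0], d2 = (nd > 1) ? dims[1] : 1, d3 = (nd > 2) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<double> g(n);
  bool any_set = false;
  for (R_xlen_t i = 0; i < n; i++) {
    if (mask[i] == TRUE) { g[i] = 0.0; any_set = true; }
    else g[i] = INF_VAL;
  }
  NumericVector out(n);
  if (!any_set) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }

  const int maxdim = std::max(d1, std::max(d2, d3));
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  // pass along axis 1 (fastest-varying)
  for (int k3 = 0; k3 < d3; k3++) {
    for (int k2 = 0; k2 < d2; k2++) {
      const R_xlen_t base = (R_xlen_t)d1 * (k2 + (R_xlen_t)d2 * k3);
      for (int i = 0; i < d1; i++) f[i] = g[base + i];
      f.resize(d1);
      dt1d(f, d, v, z, spacing[0]);
      for (int i = 0; i < d1; i++) g[base + i] = d[i];
      f.resize(maxdim);
    }
  }
  // pass along axis 2
  if (nd > 1) {
    for (int k3 = 0; k3 < d3; k3++) {
      for (int k1 = 0; k1 < d1; k1++) {
        const R_xlen_t base = k1 + (R_xlen_t)d1 * d2 * k3;
        for (int i = 0; i < d2; i++) f[i] = g[base + (R_xlen_t)d1 * i];
        f.resize(d2);
        dt1d(f, d, v, z, spacing[1]);
        for (int i = 0; i < d2; i++) g[base + (R_xlen_t)d1 * i] = d[i];
        f.resize(maxdim);
      }
    }
  }
  // pass along axis 3
  if (nd > 2) {
    const R_xlen_t stride = (R_xlen_t)d1 * d2;
    for (int k2 = 0; k2 < d2; k2++) {
      for (int k1 = 0; k1 < d1; k1++) {
        const R_xlen_t base = k1 + (R_xlen_t)d1 * k2;
        for (int i = 0; i < d3; i++) f[i] = g[base + stride * i];
        f.resize(d3);
        dt1d(f, d, v, z, spacing[2]);
        for (int i = 0; i < d3; i++) g[base + stride * i] = d[i];
        f.resize(maxdim);
      }
    }
  }

  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (g[i] >= INF_VAL / 2.0) ? R_PosInf : g[i];
  return out;
}

// 8-connected component labelling of a logical matrix (column-major).
// Returns an integer matrix-shaped vector: 0 background, 1..k components.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerVector label8_cpp(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 2) stop("dims must have length 2");
  const int nr = dims[0], nc = dims[1];
  const R_xlen_t n = (R_xlen_t)nr * nc;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int r = (int)(p % nr), c = (int)(p / nr);
      for (int dc = -1; dc <= 1; dc++) {
        for (int dr = -1; dr <= 1; dr++) {
          if (dr == 0 && dc == 0) continue;
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const R_xlen_t q = rr + (R_xlen_t)nr * cc;
          if (mask[q] == TRUE && lab[q] == 0) {
            lab[q] = next;
            stack.push_back(q);
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
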