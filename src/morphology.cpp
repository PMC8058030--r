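#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D morphology primitives shared by body-contour extraction, contour
// harmonization and the surface-distance metrics. All arrays are logical
// vectors carrying a dim attribute (nx, ny, nz); labels are 1-based,
// 0 = background.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();

  // neighbour offsets
  std::vector<std::array<int,3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int current = 0;
  std::vector<int> stack;
  stack.reserve(1024);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int p = lin(i, j, k, nx, ny);
        if (!mask[p] || labels[p] != 0) continue;
        ++current;
        labels[p] = current;
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          int qi = q % nx, qj = (q / nx) % ny, qk = q / (nx * ny);
          for (const auto &d : nb) {
            int ii = qi + d[0], jj = qj + d[1], kk = qk + d[2];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            int r = lin(ii, jj, kk, nx, ny);
            if (mask[r] && labels[r] == 0) {
              labels[r] = current;
              stack.push_back(r);
            }
          }
        }
      }
  return labels;
}

// Fill interior holes slice by slice: background connected (4-neighbourhood)
// to the slice border stays background, everything else becomes foreground.
// [[Rcpp::export(name = ".cpp_fill_holes_2d")]]
LogicalVector cpp_fill_holes_2d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];

  LogicalVector out = clone(mask);
  out.attr("dim") = dims;
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;

  for (int k = 0; k < nz; ++k) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    const int base = nx * ny * k;
    // seed from border background pixels
    for (int i = 0; i < nx; ++i)
      for (int j : {0, ny - 1}) {
        int p = i + nx * j;
        if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    for (int j = 0; j < ny; ++j)
      for (int i : {0, nx - 1}) {
        int p = i + nx * j;
        if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      int qi = q % nx, qj = q / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int ii = qi + di[t], jj = qj + dj[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        int p = ii + nx * jj;
        if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
      }
    }
    for (int p = 0; p < nx * ny; ++p)
      if (!mask[base + p] && !reach[p]) out[base + p] = true;
  }
  return out;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, squared
// distances, separable) with per-axis physical spacing. Returns, for every
// voxel, the distance in mm to the nearest TRUE voxel; Inf if none.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double s) {
  const double BIG = 1e30;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double fq = f[q] + (double)q * q * s * s;
    while (true) {
      double fv = f[v[k]] + (double)v[k] * v[k] * s * s;
      double sep = (fq - fv) / (2.0 * s * (q - v[k]));
      if (sep <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -BIG; z[1] = BIG; goto placed; }
      } else {
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = BIG;
        goto placed;
      }
    }
    placed:;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q * s) ++k;
    double dq = (double)(q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector feature, NumericVector spacing) {
  IntegerVector dims = feature.attr("dim");
  if (dims.size() != 3) stop("feature must be a 3D array");
  if (spacing.size() != 3) stop("spacing must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;

  NumericVector out(feature.size());
  out.attr("dim") = dims;
  for (R_xlen_t p = 0; p < feature.size(); ++p)
    out[p] = feature[p] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x-axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[lin(i, j, k, nx, ny)] = d[i];
    }
  // y-axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[lin(i, j, k, nx, ny)] = d[j];
    }
  // z-axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = out[lin(i, j, k, nx, ny)];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[lin(i, j, k, nx, ny)] = d[k];
    }

  for (R_xlen_t p = 0; p < out.size(); ++p)
    out[p] = out[p] >= INF ? R_PosInf : std::sqrt(out[p]);
  return out;
}
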