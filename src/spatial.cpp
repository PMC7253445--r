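// Spatial primitives on regular voxel grids: first-nearest-neighbour (face
// adjacency) connected components and separable Gaussian smoothing with
// edge renormalization.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Label 6-connected components of a binary 3D mask. Returns labels 1..n_comp
// (0 = background) in a vector the same length as `mask`.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (mask.size() != nvox) stop("mask length does not match dims");
  IntegerVector lab(nvox, 0);
  std::vector<int> stack;
  int next = 0;
  const int dxs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, -1, 1};
  for (int v = 0; v < nvox; ++v) {
    if (!mask[v] || lab[v] != 0) continue;
    ++next;
    lab[v] = next;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      const int cur = stack.back();
      stack.pop_back();
      const int x = cur % nx;
      const int y = (cur / nx) % ny;
      const int z = cur / (nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int xx = x + dxs[d], yy = y + dys[d], zz = z + dzs[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int nb = xx + nx * (yy + ny * zz);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}

static void smooth_axis(std::vector<double>& vol, int nx, int ny, int nz,
                        int axis, const std::vector<double>& w,
                        const std::vector<double>& inv_wsum) {
  const int R = (static_cast<int>(w.size()) - 1) / 2;
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
  std::vector<double> line(len);
  const int n_outer = nx * ny * nz / len;
  for (int o = 0; o < n_outer; ++o) {
    // base index of this line
    int base;
    if (axis == 0) {
      base = o * nx;
    } else if (axis == 1) {
      const int x = o % nx, z = o / nx;
      base = x + nx * ny * z;
    } else {
      base = o;
    }
    double* v = vol.data() + base;
    for (int i = 0; i < len; ++i) line[i] = v[i * stride];
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      const int lo = std::max(0, i - R), hi = std::min(len - 1, i + R);
      const double* lw = w.data() + (R - i);
      for (int k = lo; k <= hi; ++k) acc += lw[k] * line[k];
      v[i * stride] = acc * inv_wsum[i];
    }
  }
}

// Direct-form-II-transposed IIR filter applied along the time axis
// (columns) of a channels x time matrix, vectorized across channels.
// Coefficients must be normalized (a[0] = 1); the initial state is zi_unit
// scaled by the first column (steady-state trick, so step inputs produce no
// start-up transient).
// [[Rcpp::export]]
NumericMatrix cpp_iir_time(NumericVector b, NumericVector a, NumericMatrix x,
                           NumericVector zi_unit) {
  const int n = b.size();
  const int nv = x.nrow(), nt = x.ncol();
  if (a.size() != n || zi_unit.size() != n - 1)
    stop("inconsistent filter coefficient lengths");
  NumericMatrix y(nv, nt);
  std::vector<double> z(static_cast<size_t>(n - 1) * nv);
  const double* x0 = &x(0, 0);
  for (int k = 0; k < n - 1; ++k)
    for (int v = 0; v < nv; ++v) z[static_cast<size_t>(k) * nv + v] =
      zi_unit[k] * x0[v];
  for (int t = 0; t < nt; ++t) {
    const double* xt = &x(0, t);
    double* yt = &y(0, t);
    for (int v = 0; v < nv; ++v) {
      const double xv = xt[v];
      const double yv = b[0] * xv + z[v];
      for (int k = 0; k < n - 2; ++k)
        z[static_cast<size_t>(k) * nv + v] =
          z[static_cast<size_t>(k + 1) * nv + v] + b[k + 1] * xv -
          a[k + 1] * yv;
      z[static_cast<size_t>(n - 2) * nv + v] = b[n - 1] * xv - a[n - 1] * yv;
      yt[v] = yv;
    }
  }
  return y;
}

// Separable Gaussian smoothing of a 3D or 4D array (dims = c(nx, ny, nz),
// nt volumes). sigma is in voxels per spatial axis. Kernel weights are
// renormalized near the edges so a spatially constant volume is unchanged.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dims,
                                  int nt, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (arr.size() != static_cast<R_xlen_t>(nvox) * nt)
    stop("array length does not match dims and nt");
  NumericVector out = clone(arr);
  std::vector<std::vector<double>> kernels(3), inv_wsums(3);
  for (int a = 0; a < 3; ++a) {
    const double s = sigma[a];
    if (s <= 0) continue;
    const int R = std::max(1, static_cast<int>(std::ceil(3.5 * s)));
    kernels[a].resize(2 * R + 1);
    for (int k = -R; k <= R; ++k)
      kernels[a][k + R] = std::exp(-0.5 * k * k / (s * s));
    const int len = (a == 0) ? nx : (a == 1) ? ny : nz;
    inv_wsums[a].resize(len);
    for (int i = 0; i < len; ++i) {
      double wsum = 0.0;
      const int lo = std::max(0, i - R), hi = std::min(len - 1, i + R);
      for (int k = lo; k <= hi; ++k) wsum += kernels[a][k - i + R];
      inv_wsums[a][i] = 1.0 / wsum;
    }
  }
  std::vector<double> vol(nvox);
  for (int t = 0; t < nt; ++t) {
    std::copy(out.begin() + static_cast<R_xlen_t>(t) * nvox,
              out.begin() + static_cast<R_xlen_t>(t + 1) * nvox, vol.begin());
    for (int a = 0; a < 3; ++a)
      if (!kernels[a].empty())
        smooth_axis(vol, nx, ny, nz, a, kernels[a], inv_wsums[a]);
    std::copy(vol.begin(), vol.end(),
              out.begin() + static_cast<R_xlen_t>(t) * nvox);
  }
  return out;
}
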