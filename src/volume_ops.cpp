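#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <array>
#include <unordered_map>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// 3D arrays arrive as R numeric vectors in column-major order:
// voxel (i,j,k), 0-based, lives at i + nx*(j + ny*k).

static inline int reflect_idx(int i, int n) {
  // mirror boundary including the edge sample (scipy 'reflect')
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, const std::vector<double>& k,
                      int axis) {
  const int r = ((int)k.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int na = n[axis], sa = stride[axis];
  for (int kz = 0; kz < nz; ++kz) {
    for (int jy = 0; jy < ny; ++jy) {
      for (int ix = 0; ix < nx; ++ix) {
        int idx3[3] = {ix, jy, kz};
        const int pos = idx3[axis];
        const int base = ix + nx * (jy + (long)ny * kz) - pos * sa;
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          const int q = reflect_idx(pos + t, na);
          acc += in[base + q * sa] * k[t + r];
        }
        out[ix + nx * (jy + (long)ny * kz)] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".sepConvolve3D")]]
NumericVector sep_convolve_3d(NumericVector vol, IntegerVector dims,
                              NumericVector kx, NumericVector ky,
                              NumericVector kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  std::vector<double> vkx(kx.begin(), kx.end());
  std::vector<double> vky(ky.begin(), ky.end());
  std::vector<double> vkz(kz.begin(), kz.end());
  conv_axis(a, b, nx, ny, nz, vkx, 0);
  conv_axis(b, a, nx, ny, nz, vky, 1);
  conv_axis(a, b, nx, ny, nz, vkz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}

// Eigenvalues of the symmetric 3x3 matrix field, sorted by |lambda|
// ascending. Uses the trigonometric closed form (stable for the smooth
// Hessian fields produced by Gaussian derivative filtering).
// [[Rcpp::export(name = ".eigSym3Field")]]
List eig_sym3_field(NumericVector xx, NumericVector yy, NumericVector zz,
                    NumericVector xy, NumericVector xz, NumericVector yz) {
  const R_xlen_t n = xx.size();
  NumericVector l1(n), l2(n), l3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double a = xx[i], b = yy[i], c = zz[i];
    const double d = xy[i], e = yz[i], f = xz[i];
    const double p1 = d * d + f * f + e * e;
    double ev[3];
    if (p1 < 1e-30) {
      ev[0] = a; ev[1] = b; ev[2] = c;
    } else {
      const double q = (a + b + c) / 3.0;
      const double p2 = (a - q) * (a - q) + (b - q) * (b - q) +
                        (c - q) * (c - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // B = (A - q I)/p ; r = det(B)/2 clamped to [-1,1]
      const double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      const double b12 = d / p, b13 = f / p, b23 = e / p;
      double r = b11 * (b22 * b33 - b23 * b23) -
                 b12 * (b12 * b33 - b23 * b13) +
                 b13 * (b12 * b23 - b22 * b13);
      r /= 2.0;
      r = std::max(-1.0, std::min(1.0, r));
      const double phi = std::acos(r) / 3.0;
      ev[0] = q + 2.0 * p * std::cos(phi);
      ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      ev[1] = 3.0 * q - ev[0] - ev[2];
    }
    std::sort(ev, ev + 3,
              [](double u, double v) { return std::fabs(u) < std::fabs(v); });
    l1[i] = ev[0]; l2[i] = ev[1]; l3[i] = ev[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

// Spherical-window local maxima: voxel v is a maximum iff
// L(v) >= L(u) for every u with ||center(u)-center(v)|| <= radius_mm,
// and L(v) > floor. Returns 0-based voxel indices.
// [[Rcpp::export(name = ".localMaximaSpherical")]]
IntegerVector local_maxima_spherical(NumericVector vol, IntegerVector dims,
                                     double spacing, double radius_mm,
                                     double floor_val) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (int)std::floor(radius_mm / spacing);
  std::vector<std::array<int, 3>> offs;
  const double r2 = radius_mm * radius_mm;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const double d2 = (double)(dx * dx + dy * dy + dz * dz) * spacing * spacing;
        if (d2 <= r2 + 1e-12) offs.push_back({dx, dy, dz});
      }
  std::vector<int> out;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const long idx = i + nx * (j + (long)ny * k);
        const double v = vol[idx];
        if (!(v > floor_val)) continue;
        bool is_max = true;
        for (const auto& o : offs) {
          const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          if (vol[ii + nx * (jj + (long)ny * kk)] > v) { is_max = false; break; }
        }
        if (is_max) out.push_back((int)idx);
      }
  return IntegerVector(out.begin(), out.end());
}

// 26-connected components over a set of voxel indices (0-based); returns a
// component id per input voxel (1-based component numbering).
// [[Rcpp::export(name = ".labelComponents26")]]
IntegerVector label_components_26(IntegerVector voxels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<long, int> pos;  // voxel index -> position in input
  for (int t = 0; t < voxels.size(); ++t) pos[(long)voxels[t]] = t;
  IntegerVector comp(voxels.size(), 0);
  int next = 0;
  for (int t = 0; t < voxels.size(); ++t) {
    if (comp[t] != 0) continue;
    comp[t] = ++next;
    std::queue<long> q;
    q.push((long)voxels[t]);
    while (!q.empty()) {
      const long cur = q.front(); q.pop();
      const int i = cur % nx, j = (cur / nx) % ny, k = cur / ((long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int ii = i + dx, jj = j + dy, kk = k + dz;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const long nb = ii + nx * (jj + (long)ny * kk);
            auto it = pos.find(nb);
            if (it != pos.end() && comp[it->second] == 0) {
              comp[it->second] = next;
              q.push(nb);
            }
          }
    }
  }
  return comp;
}

// ---- Felzenszwalb & Huttenlocher 1D squared distance transform ----
// "Absent" samples are encoded as a large finite value (DT_BIG), which keeps
// the lower-envelope recursion free of special cases; DT_BIG dwarfs any
// attainable squared voxel distance on practical grids.
static const double DT_BIG = 1e15;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    const double dq = q - v[j];
    d[q] = dq * dq + f[v[j]];
  }
}

// Squared Euclidean distance (in voxel units) to the nearest nonzero voxel.
// [[Rcpp::export(name = ".edtSquared3D")]]
NumericVector edt_squared_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? 0.0 : DT_BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), o(nmax);
  // axis x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const long base = nx * (j + (long)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f, o, nx);
      for (int i = 0; i < nx; ++i) d[base + i] = o[i];
    }
  // axis y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const long base = i + (long)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (long)j * nx];
      dt1d(f, o, ny);
      for (int j = 0; j < ny; ++j) d[base + (long)j * nx] = o[j];
    }
  // axis z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const long base = i + (long)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + (long)k * nx * ny];
      dt1d(f, o, nz);
      for (int k = 0; k < nz; ++k) d[base + (long)k * nx * ny] = o[k];
    }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dims;
  return out;
}

// Additive boosted-stump score F(x) for a matrix of feature rows.
// [[Rcpp::export(name = ".boostScore")]]
NumericVector boost_score(NumericMatrix X, IntegerVector feat,
                          NumericVector thr, NumericVector resp_ge,
                          NumericVector resp_lt) {
  const int n = X.nrow(), m = feat.size();
  NumericVector F(n);
  for (int s = 0; s < m; ++s) {
    const int f = feat[s];  // 0-based column
    const double t = thr[s], a = resp_ge[s], b = resp_lt[s];
    NumericMatrix::Column col = X.column(f);
    for (int i = 0; i < n; ++i) F[i] += (col[i] >= t) ? a : b;
  }
  return F;
}

// Oblique-plane patch extraction by trilinear interpolation with zero
// padding outside the volume. Sample (i,j), 0-based, lies at
// center + (i - (size-1)/2) * step * u + (j - (size-1)/2) * step * v  [mm],
// and world position of voxel index q (0-based) is (q + 0.5) * spacing.
// [[Rcpp::export(name = ".samplePlane")]]
NumericMatrix sample_plane(NumericVector vol, IntegerVector dims,
                           double spacing, NumericVector center_mm,
                           NumericVector u, NumericVector v, int size,
                           double step_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double half = (size - 1) / 2.0;
  NumericMatrix out(size, size);
  for (int j = 0; j < size; ++j) {
    for (int i = 0; i < size; ++i) {
      double p[3];
      for (int a = 0; a < 3; ++a)
        p[a] = center_mm[a] + (i - half) * step_mm * u[a] +
               (j - half) * step_mm * v[a];
      // continuous 0-based voxel coordinate
      const double fx = p[0] / spacing - 0.5;
      const double fy = p[1] / spacing - 0.5;
      const double fz = p[2] / spacing - 0.5;
      const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
                z0 = (int)std::floor(fz);
      const double wx = fx - x0, wy = fy - y0, wz = fz - z0;
      double acc = 0.0;
      for (int dz = 0; dz <= 1; ++dz)
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
            if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
              continue;  // zero padding
            const double w = (dx ? wx : 1.0 - wx) * (dy ? wy : 1.0 - wy) *
                             (dz ? wz : 1.0 - wz);
            acc += w * vol[xi + nx * (yi + (long)ny * zi)];
          }
      out(i, j) = acc;
    }
  }
  return out;
}
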