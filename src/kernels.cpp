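#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Column-major 3D indexing throughout: idx = x + nx*(y + ny*z), 0-based.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable 3D convolution with reflecting boundaries. Kernels are 1D and
// applied along x, then y, then z. Used to turn white noise into a Gaussian
// random field with a controlled correlation length.
// [[Rcpp::export]]
NumericVector cpp_convolve_sep3(NumericVector arr, IntegerVector dim,
                                NumericVector kx, NumericVector ky,
                                NumericVector kz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector a = clone(arr);
  NumericVector b(a.size());

  // helper lambda via macro-free loop: reflect index into [0, n-1]
  auto reflect = [](int i, int n) {
    if (n == 1) return 0;
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };

  // x pass
  {
    const int h = (kx.size() - 1) / 2;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = 0; t < kx.size(); ++t)
            s += kx[t] * a[reflect(x + t - h, nx) + (size_t)nx * (y + (size_t)ny * z)];
          b[x + (size_t)nx * (y + (size_t)ny * z)] = s;
        }
    std::swap(a, b);
  }
  // y pass
  {
    const int h = (ky.size() - 1) / 2;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = 0; t < ky.size(); ++t)
            s += ky[t] * a[x + (size_t)nx * (reflect(y + t - h, ny) + (size_t)ny * z)];
          b[x + (size_t)nx * (y + (size_t)ny * z)] = s;
        }
    std::swap(a, b);
  }
  // z pass
  {
    const int h = (kz.size() - 1) / 2;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = 0; t < kz.size(); ++t)
            s += kz[t] * a[x + (size_t)nx * (y + (size_t)ny * reflect(z + t - h, nz))];
          b[x + (size_t)nx * (y + (size_t)ny * z)] = s;
        }
    std::swap(a, b);
  }
  return a;
}

// Trilinear resampling onto an isotropic grid. Voxel centers sit at
// (i + 0.5) * spacing (half-voxel-centered); source indices are clamped at
// the borders so the physical extent is preserved within one voxel.
// [[Rcpp::export]]
NumericVector cpp_reslice_trilinear(NumericVector arr, IntegerVector dim,
                                    NumericVector spacing, NumericVector odim,
                                    double target) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = (int)odim[0], my = (int)odim[1], mz = (int)odim[2];
  NumericVector out((size_t)mx * my * mz);
  for (int z = 0; z < mz; ++z) {
    double fz = (z + 0.5) * target / spacing[2] - 0.5;
    int z0 = clampi((int)std::floor(fz), 0, nz - 1);
    int z1 = clampi(z0 + 1, 0, nz - 1);
    double wz = fz - std::floor(fz);
    if (fz < 0) { z0 = z1 = 0; wz = 0; }
    if (fz > nz - 1) { z0 = z1 = nz - 1; wz = 0; }
    for (int y = 0; y < my; ++y) {
      double fy = (y + 0.5) * target / spacing[1] - 0.5;
      int y0 = clampi((int)std::floor(fy), 0, ny - 1);
      int y1 = clampi(y0 + 1, 0, ny - 1);
      double wy = fy - std::floor(fy);
      if (fy < 0) { y0 = y1 = 0; wy = 0; }
      if (fy > ny - 1) { y0 = y1 = ny - 1; wy = 0; }
      for (int x = 0; x < mx; ++x) {
        double fx = (x + 0.5) * target / spacing[0] - 0.5;
        int x0 = clampi((int)std::floor(fx), 0, nx - 1);
        int x1 = clampi(x0 + 1, 0, nx - 1);
        double wx = fx - std::floor(fx);
        if (fx < 0) { x0 = x1 = 0; wx = 0; }
        if (fx > nx - 1) { x0 = x1 = nx - 1; wx = 0; }
        double c00 = arr[x0 + (size_t)nx * (y0 + (size_t)ny * z0)] * (1 - wx) +
                     arr[x1 + (size_t)nx * (y0 + (size_t)ny * z0)] * wx;
        double c10 = arr[x0 + (size_t)nx * (y1 + (size_t)ny * z0)] * (1 - wx) +
                     arr[x1 + (size_t)nx * (y1 + (size_t)ny * z0)] * wx;
        double c01 = arr[x0 + (size_t)nx * (y0 + (size_t)ny * z1)] * (1 - wx) +
                     arr[x1 + (size_t)nx * (y0 + (size_t)ny * z1)] * wx;
        double c11 = arr[x0 + (size_t)nx * (y1 + (size_t)ny * z1)] * (1 - wx) +
                     arr[x1 + (size_t)nx * (y1 + (size_t)ny * z1)] * wx;
        out[x + (size_t)mx * (y + (size_t)my * z)] =
          (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
          (c01 * (1 - wy) + c11 * wy) * wz;
      }
    }
  }
  return out;
}

// Nearest-neighbor resampling (for masks), same grid convention as above.
// [[Rcpp::export]]
IntegerVector cpp_reslice_nn(IntegerVector arr, IntegerVector dim,
                             NumericVector spacing, NumericVector odim,
                             double target) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = (int)odim[0], my = (int)odim[1], mz = (int)odim[2];
  IntegerVector out((size_t)mx * my * mz);
  for (int z = 0; z < mz; ++z) {
    int sz = clampi((int)std::lround((z + 0.5) * target / spacing[2] - 0.5), 0, nz - 1);
    for (int y = 0; y < my; ++y) {
      int sy = clampi((int)std::lround((y + 0.5) * target / spacing[1] - 0.5), 0, ny - 1);
      for (int x = 0; x < mx; ++x) {
        int sx = clampi((int)std::lround((x + 0.5) * target / spacing[0] - 0.5), 0, nx - 1);
        out[x + (size_t)mx * (y + (size_t)my * z)] =
          arr[sx + (size_t)nx * (sy + (size_t)ny * sz)];
      }
    }
  }
  return out;
}

// Gray-level co-occurrence counts pooled over the 13 unique 3D unit-offset
// directions at distance 1, accumulated symmetrically. Only voxel pairs
// where both ends are inside the mask contribute. Levels are 1..G (0 = out).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int OFF[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {1, -1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
  NumericMatrix M(G, G);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l1 = levels[x + (size_t)nx * (y + (size_t)ny * z)];
        if (l1 <= 0) continue;
        for (int o = 0; o < 13; ++o) {
          int xx = x + OFF[o][0], yy = y + OFF[o][1], zz = z + OFF[o][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int l2 = levels[xx + (size_t)nx * (yy + (size_t)ny * zz)];
          if (l2 <= 0) continue;
          M(l1 - 1, l2 - 1) += 1.0;
          M(l2 - 1, l1 - 1) += 1.0;
        }
      }
  return M;
}

// Neighborhood gray-tone difference table over the 26-neighborhood.
// Returns per level i: n_i (count of voxels of level i that have at least
// one in-mask neighbor) and s_i (summed |i - mean neighborhood gray tone|).
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector n(G), s(G);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = levels[x + (size_t)nx * (y + (size_t)ny * z)];
        if (l <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              int l2 = levels[xx + (size_t)nx * (yy + (size_t)ny * zz)];
              if (l2 <= 0) continue;
              sum += l2;
              ++cnt;
            }
        if (cnt > 0) {
          n[l - 1] += 1;
          s[l - 1] += std::fabs((double)l - sum / cnt);
        }
      }
  return List::create(_["n"] = n, _["s"] = s);
}

// Gray-level size zones: 26-connected components of equal gray level.
// Returns one (level, size) pair per zone.
// [[Rcpp::export]]
List cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<char> seen(N, 0);
  std::vector<int> zlevel, zsize;
  std::queue<size_t> q;
  for (size_t i = 0; i < N; ++i) {
    if (seen[i] || levels[i] <= 0) continue;
    const int lev = levels[i];
    int size = 0;
    seen[i] = 1;
    q.push(i);
    while (!q.empty()) {
      size_t c = q.front();
      q.pop();
      ++size;
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((size_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            size_t j = xx + (size_t)nx * (yy + (size_t)ny * zz);
            if (!seen[j] && levels[j] == lev) {
              seen[j] = 1;
              q.push(j);
            }
          }
    }
    zlevel.push_back(lev);
    zsize.push_back(size);
  }
  return List::create(_["level"] = wrap(zlevel), _["size"] = wrap(zsize));
}
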