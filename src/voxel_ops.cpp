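// Low-level voxel kernels shared by the synthetic generator, the segmenter
// and the morphometry code. All arrays are R arrays with dim = c(nz, ny, nx)
// (axis order Z, Y, X), addressed as i = z + nz*(y + ny*x), 0-based.
// Physical spacing is passed as c(sz, sy, sx) in micrometres.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

static const double BIG = 1e20;

struct Dim {
  int nz, ny, nx;
  R_xlen_t n;
};
static Dim get_dim(const IntegerVector& dim) {
  Dim d;
  d.nz = dim[0]; d.ny = dim[1]; d.nx = dim[2];
  d.n = (R_xlen_t)d.nz * d.ny * d.nx;
  return d;
}
static inline R_xlen_t lin(const Dim& d, int z, int y, int x) {
  return (R_xlen_t)z + (R_xlen_t)d.nz * ((R_xlen_t)y + (R_xlen_t)d.ny * x);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable per axis, anisotropic spacing.
// Returns squared distance from every voxel to the nearest feature voxel.
// ---------------------------------------------------------------------------
static void dt1d(std::vector<double>& f, std::vector<double>& out, int n, double s2,
                 std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -BIG; zb[1] = BIG;
  for (int q = 1; q < n; ++q) {
    while (true) {
      int p = v[k];
      double sint = ((f[q] - f[p]) / s2 + (double)q * q - (double)p * p) /
                    (2.0 * (q - p));
      if (sint <= zb[k] && k > 0) {
        --k;
      } else {
        if (sint <= zb[k]) { // k == 0, replace
          v[0] = q; zb[0] = -BIG; zb[1] = BIG;
        } else {
          ++k; v[k] = q; zb[k] = sint; zb[k + 1] = BIG;
        }
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    out[q] = f[p] + s2 * (q - p) * (q - p);
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim, NumericVector spacing,
                         bool invert = false, bool take_sqrt = false) {
  Dim d = get_dim(dim);
  NumericVector D(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) D[i] = (feature[i] != invert) ? 0.0 : BIG;
  int nmax = std::max(d.nz, std::max(d.ny, d.nx));
  std::vector<double> f(nmax), out(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // axis Z (stride 1)
  {
    double s2 = spacing[0] * spacing[0];
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y) {
        R_xlen_t base = lin(d, 0, y, x);
        for (int z = 0; z < d.nz; ++z) f[z] = D[base + z];
        dt1d(f, out, d.nz, s2, v, zb);
        for (int z = 0; z < d.nz; ++z) D[base + z] = out[z];
      }
  }
  // axis Y (stride nz)
  {
    double s2 = spacing[1] * spacing[1];
    for (int x = 0; x < d.nx; ++x)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t base = lin(d, z, 0, x);
        for (int y = 0; y < d.ny; ++y) f[y] = D[base + (R_xlen_t)y * d.nz];
        dt1d(f, out, d.ny, s2, v, zb);
        for (int y = 0; y < d.ny; ++y) D[base + (R_xlen_t)y * d.nz] = out[y];
      }
  }
  // axis X (stride nz*ny)
  {
    double s2 = spacing[2] * spacing[2];
    R_xlen_t st = (R_xlen_t)d.nz * d.ny;
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t base = lin(d, z, y, 0);
        for (int x = 0; x < d.nx; ++x) f[x] = D[base + (R_xlen_t)x * st];
        dt1d(f, out, d.nx, s2, v, zb);
        for (int x = 0; x < d.nx; ++x) D[base + (R_xlen_t)x * st] = out[x];
      }
  }
  if (take_sqrt)
    for (R_xlen_t i = 0; i < d.n; ++i) D[i] = std::sqrt(D[i]);
  return D;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, reflecting boundary, sigma per axis in voxels.
// ---------------------------------------------------------------------------
static void smooth_axis(double* a, double* b, const Dim& d,
                        int axis, double sigma, bool& in_a) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double sum = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    sum += ker[i + r];
  }
  for (double& k : ker) k /= sum;
  int n = axis == 0 ? d.nz : (axis == 1 ? d.ny : d.nx);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? d.nz : (R_xlen_t)d.nz * d.ny);
  int n1 = axis == 0 ? d.ny : d.nz;
  int n2 = axis == 2 ? d.ny : d.nx;
  double* src = in_a ? a : b;
  double* dst = in_a ? b : a;
  for (int j2 = 0; j2 < n2; ++j2)
    for (int j1 = 0; j1 < n1; ++j1) {
      R_xlen_t base;
      if (axis == 0) base = lin(d, 0, j1, j2);
      else if (axis == 1) base = lin(d, j1, 0, j2);
      else base = lin(d, j1, j2, 0);
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int ii = i + k;
          if (ii < 0) ii = -ii - 1;
          if (ii >= n) ii = 2 * n - ii - 1;
          acc += ker[k + r] * src[base + (R_xlen_t)ii * stride];
        }
        dst[base + (R_xlen_t)i * stride] = acc;
      }
    }
  in_a = !in_a;
}

// Return freed heap pages to the OS. R's gc() releases memory to glibc's
// allocator, but mid-size chunks (e.g. TIFF page matrices) stay in the heap
// arena and inflate resident memory across the multi-gigabyte pipeline
// stages; malloc_trim hands those pages back. No-op off glibc.
// [[Rcpp::export]]
void cpp_malloc_trim() {
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// `in_place = true` smooths directly in `img`'s buffer (saving one full-size
// allocation); only safe when the caller holds the sole reference.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dim, NumericVector sigma_vox,
                          bool in_place = false) {
  Dim d = get_dim(dim);
  NumericVector out = in_place ? img : NumericVector(d.n);
  if (!in_place) std::copy(img.begin(), img.end(), out.begin());
  std::vector<double> scratch(d.n);
  bool in_a = true; // tracks whether the current values live in `out`
  smooth_axis(REAL(out), scratch.data(), d, 0, sigma_vox[0], in_a);
  smooth_axis(REAL(out), scratch.data(), d, 1, sigma_vox[1], in_a);
  smooth_axis(REAL(out), scratch.data(), d, 2, sigma_vox[2], in_a);
  if (!in_a) std::copy(scratch.begin(), scratch.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Binary dilation by a physical radius (ball structuring element).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_dilate_ball(LogicalVector mask, IntegerVector dim, NumericVector spacing,
                              double radius, bool ring = false) {
  Dim d = get_dim(dim);
  std::vector<std::array<int, 3>> off;
  int rz = (int)std::floor(radius / spacing[0]);
  int ry = (int)std::floor(radius / spacing[1]);
  int rx = (int)std::floor(radius / spacing[2]);
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double dd = dz * spacing[0] * dz * spacing[0] + dy * spacing[1] * dy * spacing[1] +
                    dx * spacing[2] * dx * spacing[2];
        if (dd <= radius * radius) off.push_back({dz, dy, dx});
      }
  LogicalVector out(d.n);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        if (!mask[i]) continue;
        for (auto& o : off) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
          out[lin(d, zz, yy, xx)] = TRUE;
        }
      }
  if (ring) // keep only the dilation ring outside the original mask
    for (R_xlen_t i = 0; i < d.n; ++i)
      if (mask[i]) out[i] = FALSE;
  return out;
}

// ---------------------------------------------------------------------------
// Finite range + histogram for Otsu thresholding in one pass, with
// bin = clamp(1 + trunc((v-lo)/(hi-lo)*n), 1, n). Computed in C++ because
// the equivalent R expressions (`range(x, finite=TRUE)`, binning arithmetic)
// allocate several full-size temporaries, which matters on 10^8-voxel stacks.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_otsu_hist(NumericVector x, int n_bins) {
  double lo = R_PosInf, hi = R_NegInf;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (!R_finite(v)) continue;
    if (v < lo) lo = v;
    if (v > hi) hi = v;
  }
  IntegerVector h(n_bins);
  if (R_finite(lo) && R_finite(hi) && hi > lo) {
    double inv = n_bins / (hi - lo);
    for (R_xlen_t i = 0; i < x.size(); ++i) {
      double v = x[i];
      if (!R_finite(v)) continue;
      int b = 1 + (int)((v - lo) * inv);
      if (b < 1) b = 1;
      if (b > n_bins) b = n_bins;
      ++h[b - 1];
    }
  }
  return List::create(Named("range") = NumericVector::create(lo, hi),
                      Named("counts") = h);
}

// ---------------------------------------------------------------------------
// 26-connected components of a binary mask, labelled 1..K in scan order.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  Dim d = get_dim(dim);
  IntegerVector lab(d.n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t p = stack.back();
          stack.pop_back();
          int pz = (int)(p % d.nz);
          int py = (int)((p / d.nz) % d.ny);
          int px = (int)(p / ((R_xlen_t)d.nz * d.ny));
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                int zz = pz + dz, yy = py + dy, xx = px + dx;
                if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
                  continue;
                R_xlen_t q = lin(d, zz, yy, xx);
                if (mask[q] && !lab[q]) {
                  lab[q] = next;
                  stack.push_back(q);
                }
              }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Fill interior cavities: background 6-connected to the stack border stays
// background, enclosed background becomes foreground.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  Dim d = get_dim(dim);
  std::vector<char> reach(d.n, 0);
  std::vector<R_xlen_t> stack;
  auto push_if = [&](int z, int y, int x) {
    if (z < 0 || z >= d.nz || y < 0 || y >= d.ny || x < 0 || x >= d.nx) return;
    R_xlen_t i = lin(d, z, y, x);
    if (!mask[i] && !reach[i]) {
      reach[i] = 1;
      stack.push_back(i);
    }
  };
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      push_if(0, y, x);
      push_if(d.nz - 1, y, x);
    }
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      push_if(z, 0, x);
      push_if(z, d.ny - 1, x);
    }
  for (int y = 0; y < d.ny; ++y)
    for (int z = 0; z < d.nz; ++z) {
      push_if(z, y, 0);
      push_if(z, y, d.nx - 1);
    }
  while (!stack.empty()) {
    R_xlen_t p = stack.back();
    stack.pop_back();
    int pz = (int)(p % d.nz);
    int py = (int)((p / d.nz) % d.ny);
    int px = (int)(p / ((R_xlen_t)d.nz * d.ny));
    push_if(pz - 1, py, px); push_if(pz + 1, py, px);
    push_if(pz, py - 1, px); push_if(pz, py + 1, px);
    push_if(pz, py, px - 1); push_if(pz, py, px + 1);
  }
  LogicalVector out(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) out[i] = mask[i] || !reach[i];
  return out;
}

// ---------------------------------------------------------------------------
// Voxels lying on a wall between two different positive labels (6-neighbour).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_interface6(IntegerVector labels, IntegerVector dim) {
  Dim d = get_dim(dim);
  LogicalVector out(d.n);
  const int offs[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        int a = labels[i];
        if (a <= 0) continue;
        for (int k = 0; k < 3; ++k) {
          int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
          if (zz >= d.nz || yy >= d.ny || xx >= d.nx) continue;
          R_xlen_t j = lin(d, zz, yy, xx);
          int b = labels[j];
          if (b > 0 && b != a) {
            out[i] = TRUE;
            out[j] = TRUE;
          }
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Carve extracellular walls in place: voxels within `radius` of a face
// between two different positive labels are set to background.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
void cpp_carve_walls(IntegerVector labels, IntegerVector dim, NumericVector spacing,
                     double radius) {
  Dim d = get_dim(dim);
  std::vector<char> iface(d.n, 0);
  const int offs[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  bool any_iface = false;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        int a = labels[i];
        if (a <= 0) continue;
        for (int k = 0; k < 3; ++k) {
          int zz = z + offs[k][0], yy = y + offs[k][1], xx = x + offs[k][2];
          if (zz >= d.nz || yy >= d.ny || xx >= d.nx) continue;
          R_xlen_t j = lin(d, zz, yy, xx);
          int b = labels[j];
          if (b > 0 && b != a) {
            iface[i] = 1;
            iface[j] = 1;
            any_iface = true;
          }
        }
      }
  if (!any_iface) return;
  std::vector<std::array<int, 3>> off;
  if (radius > 0) {
    int rz = (int)std::floor(radius / spacing[0]);
    int ry = (int)std::floor(radius / spacing[1]);
    int rx = (int)std::floor(radius / spacing[2]);
    for (int dz = -rz; dz <= rz; ++dz)
      for (int dy = -ry; dy <= ry; ++dy)
        for (int dx = -rx; dx <= rx; ++dx) {
          if (!dz && !dy && !dx) continue;
          double dd = dz * spacing[0] * dz * spacing[0] +
                      dy * spacing[1] * dy * spacing[1] +
                      dx * spacing[2] * dx * spacing[2];
          if (dd <= radius * radius) off.push_back({dz, dy, dx});
        }
  }
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        if (!iface[i]) continue;
        labels[i] = 0;
        for (auto& o : off) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
            continue;
          labels[lin(d, zz, yy, xx)] = 0;
        }
      }
}

// ---------------------------------------------------------------------------
// Per-label voxel counts, centroid sums (0-based index units), border contact.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector labels, IntegerVector dim) {
  Dim d = get_dim(dim);
  int K = 0;
  for (R_xlen_t i = 0; i < d.n; ++i)
    if (labels[i] > K) K = labels[i];
  NumericVector count(K), sz(K), sy(K), sx(K);
  LogicalVector border(K);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        int l = labels[lin(d, z, y, x)];
        if (l <= 0) continue;
        count[l - 1] += 1;
        sz[l - 1] += z; sy[l - 1] += y; sx[l - 1] += x;
        if (z == 0 || z == d.nz - 1 || y == 0 || y == d.ny - 1 || x == 0 || x == d.nx - 1)
          border[l - 1] = TRUE;
      }
  return List::create(_["count"] = count, _["sum_z"] = sz, _["sum_y"] = sy,
                      _["sum_x"] = sx, _["border"] = border);
}

// ---------------------------------------------------------------------------
// Crofton surface areas per label: crossing counts along a direction set,
// weighted by the spherical Voronoi solid-angle fractions of the directions.
// Each label<->different-value voxel pair along direction t contributes
// 2 * w_t * (voxel_volume / step_length) to that label's surface.
// Out-of-bounds neighbours count as background so closed surfaces at the
// stack faces are included.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_crofton_areas(IntegerVector labels, IntegerVector dim, NumericVector spacing,
                                IntegerMatrix dirs, NumericVector wts) {
  Dim d = get_dim(dim);
  int K = 0;
  for (R_xlen_t i = 0; i < d.n; ++i)
    if (labels[i] > K) K = labels[i];
  NumericVector area(K);
  double voxvol = spacing[0] * spacing[1] * spacing[2];
  for (int t = 0; t < dirs.nrow(); ++t) {
    int dz = dirs(t, 0), dy = dirs(t, 1), dx = dirs(t, 2);
    double L = std::sqrt(dz * spacing[0] * dz * spacing[0] + dy * spacing[1] * dy * spacing[1] +
                         dx * spacing[2] * dx * spacing[2]);
    double c = 2.0 * wts[t] * voxvol / L;
    for (int x = 0; x < d.nx; ++x)
      for (int y = 0; y < d.ny; ++y)
        for (int z = 0; z < d.nz; ++z) {
          R_xlen_t i = lin(d, z, y, x);
          int a = labels[i];
          int zz = z + dz, yy = y + dy, xx = x + dx;
          bool in = zz >= 0 && zz < d.nz && yy >= 0 && yy < d.ny && xx >= 0 && xx < d.nx;
          int b = in ? labels[lin(d, zz, yy, xx)] : 0;
          if (a != b) {
            if (a > 0) area[a - 1] += c;
            if (b > 0) area[b - 1] += c;
          }
          // the opposite out-of-bounds side: pair (i - dir) outside the stack
          int z2 = z - dz, y2 = y - dy, x2 = x - dx;
          bool in2 = z2 >= 0 && z2 < d.nz && y2 >= 0 && y2 < d.ny && x2 >= 0 && x2 < d.nx;
          if (!in2 && a > 0) area[a - 1] += c;
        }
  }
  return area;
}

// ---------------------------------------------------------------------------
// Ball-clipped Laguerre (power diagram) assignment. Voxel centres sit at
// index * spacing. A voxel belongs to the seed with the smallest power
// distance |x-c|^2 - r^2 among seeds whose ball contains it.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_laguerre_assign(IntegerVector dim, NumericVector spacing,
                                  NumericMatrix centers, NumericVector radii) {
  Dim d = get_dim(dim);
  IntegerVector lab(d.n);
  std::vector<float> best(d.n, 1e30f);
  int K = centers.nrow();
  for (int k = 0; k < K; ++k) {
    double cz = centers(k, 0), cy = centers(k, 1), cx = centers(k, 2);
    double r = radii[k], r2 = r * r;
    int z0 = std::max(0, (int)std::ceil((cz - r) / spacing[0]));
    int z1 = std::min(d.nz - 1, (int)std::floor((cz + r) / spacing[0]));
    int y0 = std::max(0, (int)std::ceil((cy - r) / spacing[1]));
    int y1 = std::min(d.ny - 1, (int)std::floor((cy + r) / spacing[1]));
    int x0 = std::max(0, (int)std::ceil((cx - r) / spacing[2]));
    int x1 = std::min(d.nx - 1, (int)std::floor((cx + r) / spacing[2]));
    for (int x = x0; x <= x1; ++x) {
      double ddx = x * spacing[2] - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = y * spacing[1] - cy;
        double dxy = ddx * ddx + ddy * ddy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double ddz = z * spacing[0] - cz;
          double d2 = dxy + ddz * ddz;
          if (d2 > r2) continue;
          float pd = (float)(d2 - r2);
          R_xlen_t i = lin(d, z, y, x);
          if (pd < best[i]) {
            best[i] = pd;
            lab[i] = k + 1;
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Digitized spheres at fixed centres (used by the ex situ packer).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_paint_spheres(IntegerVector dim, NumericVector spacing,
                                NumericMatrix centers, NumericVector radii) {
  Dim d = get_dim(dim);
  IntegerVector lab(d.n);
  for (int k = 0; k < centers.nrow(); ++k) {
    double cz = centers(k, 0), cy = centers(k, 1), cx = centers(k, 2);
    double r = radii[k], r2 = r * r;
    int z0 = std::max(0, (int)std::ceil((cz - r) / spacing[0]));
    int z1 = std::min(d.nz - 1, (int)std::floor((cz + r) / spacing[0]));
    int y0 = std::max(0, (int)std::ceil((cy - r) / spacing[1]));
    int y1 = std::min(d.ny - 1, (int)std::floor((cy + r) / spacing[1]));
    int x0 = std::max(0, (int)std::ceil((cx - r) / spacing[2]));
    int x1 = std::min(d.nx - 1, (int)std::floor((cx + r) / spacing[2]));
    for (int x = x0; x <= x1; ++x) {
      double ddx = x * spacing[2] - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = y * spacing[1] - cy;
        double dxy = ddx * ddx + ddy * ddy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; ++z) {
          double ddz = z * spacing[0] - cz;
          if (dxy + ddz * ddz <= r2) lab[lin(d, z, y, x)] = k + 1;
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Overlap (confusion) counts between two label stacks, for IoU matching.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_overlap_counts(IntegerVector a, IntegerVector b) {
  int ka = 0, kb = 0;
  R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] > ka) ka = a[i];
    if (b[i] > kb) kb = b[i];
  }
  NumericVector ca(ka), cb(kb);
  std::unordered_map<uint64_t, double> pair_n;
  for (R_xlen_t i = 0; i < n; ++i) {
    int la = a[i], lb = b[i];
    if (la > 0) ca[la - 1] += 1;
    if (lb > 0) cb[lb - 1] += 1;
    if (la > 0 && lb > 0) pair_n[((uint64_t)la << 32) | (uint32_t)lb] += 1;
  }
  R_xlen_t m = pair_n.size();
  IntegerVector pa(m), pb(m);
  NumericVector pn(m);
  R_xlen_t j = 0;
  for (auto& kv : pair_n) {
    pa[j] = (int)(kv.first >> 32);
    pb[j] = (int)(kv.first & 0xffffffffu);
    pn[j] = kv.second;
    ++j;
  }
  return List::create(_["count_a"] = ca, _["count_b"] = cb, _["pair_a"] = pa,
                      _["pair_b"] = pb, _["pair_n"] = pn);
}

// ---------------------------------------------------------------------------
// Render one channel in a single allocation: intensity where the mask is
// set, depth decay exp(-z*sz/L), additive Gaussian noise (R RNG) over a
// constant background, clipped at 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_render_channel(LogicalVector mask, IntegerVector dim, double intensity,
                                 double spacing_z, double atten_len, double noise_sd,
                                 double background) {
  Dim d = get_dim(dim);
  NumericVector out(d.n);
  std::vector<double> decay(d.nz, 1.0);
  if (R_finite(atten_len) && atten_len > 0)
    for (int z = 0; z < d.nz; ++z) decay[z] = std::exp(-z * spacing_z / atten_len);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin(d, z, y, x);
        double v = (mask[i] ? intensity : 0.0) * decay[z] + background;
        if (noise_sd > 0) v += norm_rand() * noise_sd;
        out[i] = v < 0 ? 0 : v;
      }
  return out;
}
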