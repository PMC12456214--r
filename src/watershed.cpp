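// Morphological reconstruction, regional maxima and marker-controlled
// watershed on 3D arrays (dim = c(nz, ny, nx)), 26-connectivity.
#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

struct Dim3 {
  int nz, ny, nx;
  R_xlen_t n;
};
static Dim3 dim3_of(const IntegerVector& dim) {
  Dim3 d;
  d.nz = dim[0]; d.ny = dim[1]; d.nx = dim[2];
  d.n = (R_xlen_t)d.nz * d.ny * d.nx;
  return d;
}
static inline R_xlen_t lin3(const Dim3& d, int z, int y, int x) {
  return (R_xlen_t)z + (R_xlen_t)d.nz * ((R_xlen_t)y + (R_xlen_t)d.ny * x);
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation of `marker` under `mask` (marker <=
// mask), Vincent's hybrid algorithm: raster / anti-raster sweeps then a FIFO.
// Used for h-maxima suppression of the distance map.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_hmax_reconstruct(NumericVector mask, double h, IntegerVector dim) {
  Dim3 d = dim3_of(dim);
  // marker = mask - h (clamped at 0), built in place to avoid an extra array
  NumericVector Jv(d.n);
  double* J = REAL(Jv);
  for (R_xlen_t i = 0; i < d.n; ++i) {
    double m = mask[i] - h;
    J[i] = m > 0 ? m : 0;
  }
  // neighbour offsets split by raster order (linear index = z + nz*(y + ny*x))
  std::vector<std::array<int, 3>> nminus, nplus, nall;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        std::array<int, 3> o = {dz, dy, dx};
        nall.push_back(o);
        if (dx < 0 || (dx == 0 && (dy < 0 || (dy == 0 && dz < 0))))
          nminus.push_back(o);
        else
          nplus.push_back(o);
      }
  auto sweep = [&](bool forward) {
    const auto& nb = forward ? nminus : nplus;
    for (int xi = 0; xi < d.nx; ++xi) {
      int x = forward ? xi : d.nx - 1 - xi;
      for (int yi = 0; yi < d.ny; ++yi) {
        int y = forward ? yi : d.ny - 1 - yi;
        for (int zi = 0; zi < d.nz; ++zi) {
          int z = forward ? zi : d.nz - 1 - zi;
          R_xlen_t p = lin3(d, z, y, x);
          double m = J[p];
          for (auto& o : nb) {
            int zz = z + o[0], yy = y + o[1], xx = x + o[2];
            if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
              continue;
            double v = J[lin3(d, zz, yy, xx)];
            if (v > m) m = v;
          }
          if (m > mask[p]) m = mask[p];
          J[p] = m;
        }
      }
    }
  };
  sweep(true);
  sweep(false);
  std::queue<R_xlen_t> fifo;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t p = lin3(d, z, y, x);
        for (auto& o : nplus) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx)
            continue;
          R_xlen_t q = lin3(d, zz, yy, xx);
          if (J[q] < J[p] && J[q] < mask[q]) {
            fifo.push(p);
            break;
          }
        }
      }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front();
    fifo.pop();
    int pz = (int)(p % d.nz);
    int py = (int)((p / d.nz) % d.ny);
    int px = (int)(p / ((R_xlen_t)d.nz * d.ny));
    for (auto& o : nall) {
      int zz = pz + o[0], yy = py + o[1], xx = px + o[2];
      if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
      R_xlen_t q = lin3(d, zz, yy, xx);
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], (double)mask[q]);
        fifo.push(q);
      }
    }
  }
  return Jv;
}

// ---------------------------------------------------------------------------
// Regional maxima (26-connected plateaus with no strictly greater neighbour)
// restricted to a foreground mask. Neighbours outside the mask never
// disqualify a plateau.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector img, IntegerVector dim, LogicalVector mask) {
  Dim3 d = dim3_of(dim);
  std::vector<char> state(d.n, 0); // 0 unvisited, 1 max plateau, 2 not max
  std::vector<R_xlen_t> plateau, stack;
  LogicalVector out(d.n);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = lin3(d, z, y, x);
        if (!mask[i] || state[i]) continue;
        double v = img[i];
        bool ismax = true;
        plateau.clear();
        stack.clear();
        stack.push_back(i);
        state[i] = 1;
        plateau.push_back(i);
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
                R_xlen_t q = lin3(d, zz, yy, xx);
                if (!mask[q]) continue;
                if (img[q] > v) ismax = false;
                else if (img[q] == v && !state[q]) {
                  state[q] = 1;
                  stack.push_back(q);
                  plateau.push_back(q);
                }
              }
        }
        for (R_xlen_t p : plateau) {
          state[p] = ismax ? 1 : 2;
          out[p] = ismax;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding with a bucketed queue:
// priorities are quantized to `quantum`-wide bins processed in increasing
// order, first-in first-out within a bin, so the flood is deterministic and
// runs in O(n). Each voxel enters the queue exactly once (flood-ordered
// label propagation), restricted to `mask`; markers keep their labels.
// ---------------------------------------------------------------------------
// Relabel distinct positive labels to 1..K preserving their numeric order.
// `in_place = true` mutates `lab` directly (sole-reference vectors only);
// avoids the full-size hash/subset temporaries an R-level unique() needs.
// [[Rcpp::export]]
IntegerVector cpp_relabel_sequential(IntegerVector lab, bool in_place = false) {
  IntegerVector out = in_place ? lab : clone(lab);
  int mx = 0;
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] > mx) mx = out[i];
  if (mx == 0) return out;
  std::vector<int> map(mx + 1, 0);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] > 0) map[out[i]] = 1;
  int next = 0;
  for (int l = 1; l <= mx; ++l)
    if (map[l]) map[l] = ++next;
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] > 0) out[i] = map[out[i]];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers, LogicalVector mask,
                            IntegerVector dim, double quantum = 0.25, bool negate = false) {
  Dim3 d = dim3_of(dim);
  double sgn = negate ? -1.0 : 1.0;
  IntegerVector out(d.n);
  double pmin = R_PosInf, pmax = R_NegInf;
  for (R_xlen_t i = 0; i < d.n; ++i)
    if (mask[i]) {
      double v = sgn * priority[i];
      if (v < pmin) pmin = v;
      if (v > pmax) pmax = v;
    }
  if (!R_finite(pmin)) return out; // empty mask
  int nb = (int)std::floor((pmax - pmin) / quantum) + 2;
  auto bucket_of = [&](double v) {
    v *= sgn;
    int b = (int)std::floor((v - pmin) / quantum);
    if (b < 0) b = 0;
    if (b >= nb) b = nb - 1;
    return b;
  };
  std::vector<std::queue<R_xlen_t>> buckets(nb);
  std::vector<char> queued(d.n, 0);
  R_xlen_t pending = 0;
  for (R_xlen_t i = 0; i < d.n; ++i)
    if (markers[i] > 0 && mask[i]) {
      out[i] = markers[i];
      buckets[bucket_of(priority[i])].push(i);
      queued[i] = 1;
      ++pending;
    }
  int cur = 0;
  while (pending > 0) {
    while (cur < nb && buckets[cur].empty()) ++cur;
    if (cur >= nb) break;
    R_xlen_t p = buckets[cur].front();
    buckets[cur].pop();
    --pending;
    int lab = out[p];
    int pz = (int)(p % d.nz);
    int py = (int)((p / d.nz) % d.ny);
    int px = (int)(p / ((R_xlen_t)d.nz * d.ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int zz = pz + dz, yy = py + dy, xx = px + dx;
          if (zz < 0 || zz >= d.nz || yy < 0 || yy >= d.ny || xx < 0 || xx >= d.nx) continue;
          R_xlen_t q = lin3(d, zz, yy, xx);
          if (mask[q] && !queued[q]) {
            out[q] = lab;
            int b = bucket_of(priority[q]);
            if (b < cur) b = cur; // never flood backwards in time
            buckets[b].push(q);
            queued[q] = 1;
            ++pending;
          }
        }
  }
  return out;
}
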