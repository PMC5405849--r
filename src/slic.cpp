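#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// SLIC supervoxels: localized k-means in joint (intensity, z, y, x) space.
// Grid is R column-major with dim = (nz, ny, nx) so index = z + nz*(y + ny*x).
// Seeds sit on a fixed lattice (round(n/s) per axis, evenly spaced); each
// cluster searches a window of +/- spacing around its current centre.
// Distance D^2 = d_int^2 + compactness^2 * d_spatial^2 / S^2 with S the
// geometric mean seed spacing. Deterministic: no RNG anywhere.
// Returns 0-based labels; connectivity is enforced separately.
// [[Rcpp::export]]
IntegerVector cpp_slic(NumericVector v, IntegerVector dim, IntegerVector spacing,
                       double compactness, int iterations) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const int kz = std::max(1, (int)std::lround((double)nz / sz));
  const int ky = std::max(1, (int)std::lround((double)ny / sy));
  const int kx = std::max(1, (int)std::lround((double)nx / sx));
  const int K = kz * ky * kx;
  const double stepz = (double)nz / kz, stepy = (double)ny / ky, stepx = (double)nx / kx;
  const double S = std::cbrt((double)sz * sy * sx);
  const double spat = compactness * compactness / (S * S);
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;

  std::vector<double> cz(K), cy(K), cx(K), ci(K);
  int k = 0;
  for (int ix = 0; ix < kx; ++ix)
    for (int iy = 0; iy < ky; ++iy)
      for (int iz = 0; iz < kz; ++iz, ++k) {
        cz[k] = (iz + 0.5) * stepz - 0.5;
        cy[k] = (iy + 0.5) * stepy - 0.5;
        cx[k] = (ix + 0.5) * stepx - 0.5;
        int pz = std::min(nz - 1, std::max(0, (int)std::lround(cz[k])));
        int py = std::min(ny - 1, std::max(0, (int)std::lround(cy[k])));
        int px = std::min(nx - 1, std::max(0, (int)std::lround(cx[k])));
        ci[k] = v[(R_xlen_t)pz + (R_xlen_t)nz * (py + (R_xlen_t)ny * px)];
      }

  IntegerVector labels(n);
  // initial assignment: nearest lattice cell (guarantees every voxel assigned)
  for (int x = 0; x < nx; ++x) {
    int ix = std::min(kx - 1, (int)(x / stepx));
    for (int y = 0; y < ny; ++y) {
      int iy = std::min(ky - 1, (int)(y / stepy));
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) {
        int iz = std::min(kz - 1, (int)(z / stepz));
        labels[base + z] = iz + kz * (iy + ky * ix);
      }
    }
  }

  std::vector<double> dist(n);
  std::vector<double> sz_(K), sy_(K), sx_(K), si_(K), cnt(K);
  for (int iter = 0; iter < iterations; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < K; ++c) {
      int z0 = std::max(0, (int)std::floor(cz[c]) - sz);
      int z1 = std::min(nz - 1, (int)std::ceil(cz[c]) + sz);
      int y0 = std::max(0, (int)std::floor(cy[c]) - sy);
      int y1 = std::min(ny - 1, (int)std::ceil(cy[c]) + sy);
      int x0 = std::max(0, (int)std::floor(cx[c]) - sx);
      int x1 = std::min(nx - 1, (int)std::ceil(cx[c]) + sx);
      for (int x = x0; x <= x1; ++x) {
        double dx = x - cx[c];
        for (int y = y0; y <= y1; ++y) {
          double dy = y - cy[c];
          R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
          for (int z = z0; z <= z1; ++z) {
            double dz = z - cz[c];
            double di = v[base + z] - ci[c];
            double D = di * di + spat * (dz * dz + dy * dy + dx * dx);
            if (D < dist[base + z]) {
              dist[base + z] = D;
              labels[base + z] = c;
            }
          }
        }
      }
    }
    // update centres
    std::fill(sz_.begin(), sz_.end(), 0.0);
    std::fill(sy_.begin(), sy_.end(), 0.0);
    std::fill(sx_.begin(), sx_.end(), 0.0);
    std::fill(si_.begin(), si_.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    R_xlen_t idx = 0;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z, ++idx) {
          int c = labels[idx];
          sz_[c] += z; sy_[c] += y; sx_[c] += x; si_[c] += v[idx]; cnt[c] += 1.0;
        }
    for (int c = 0; c < K; ++c) {
      if (cnt[c] > 0) {
        cz[c] = sz_[c] / cnt[c]; cy[c] = sy_[c] / cnt[c];
        cx[c] = sx_[c] / cnt[c]; ci[c] = si_[c] / cnt[c];
      }
    }
  }
  return labels;
}

// Enforce that every supervoxel is one 26-connected component. Connected
// components are found per label; the largest component of each label keeps
// it, and every other fragment is merged into the face-adjacent region with
// the closest mean intensity (ties -> lowest label id). Labels are then
// relabelled contiguous 0..K-1 in increasing original-label order.
// [[Rcpp::export]]
IntegerVector cpp_enforce_connectivity(IntegerVector labels, IntegerVector dim,
                                       NumericVector v) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> comp(n, -1);
  std::vector<double> comp_sum;
  std::vector<R_xlen_t> comp_size;
  std::vector<int> comp_label;

  // 26-connected components within equal labels (BFS, scan order => deterministic)
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (comp[start] >= 0) continue;
    int lab = labels[start];
    comp_sum.push_back(0.0);
    comp_size.push_back(0);
    comp_label.push_back(lab);
    comp[start] = ncomp;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      comp_sum[ncomp] += v[p];
      comp_size[ncomp] += 1;
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int z2 = z + dz, y2 = y + dy, x2 = x + dx;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
            R_xlen_t q = (R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
            if (comp[q] < 0 && labels[q] == lab) {
              comp[q] = ncomp;
              stack.push_back(q);
            }
          }
    }
    ++ncomp;
  }

  // keeper = largest component of each label (tie -> first in scan order)
  int maxlab = 0;
  for (int c = 0; c < ncomp; ++c) maxlab = std::max(maxlab, comp_label[c]);
  std::vector<int> keeper(maxlab + 1, -1);
  for (int c = 0; c < ncomp; ++c) {
    int lab = comp_label[c];
    if (keeper[lab] < 0 || comp_size[c] > comp_size[keeper[lab]]) keeper[lab] = c;
  }
  // assigned[c] = component id whose label this component finally takes
  std::vector<int> assigned(ncomp, -1);
  for (int lab = 0; lab <= maxlab; ++lab)
    if (keeper[lab] >= 0) assigned[keeper[lab]] = keeper[lab];

  // voxel lists per component for fragment merging passes
  std::vector<std::vector<R_xlen_t> > members(ncomp);
  for (R_xlen_t p = 0; p < n; ++p) members[comp[p]].push_back(p);

  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < ncomp; ++c) {
      if (assigned[c] >= 0) continue;
      double my_mean = comp_sum[c] / comp_size[c];
      int best = -1;
      double best_d = R_PosInf;
      int best_lab = INT_MAX;
      for (size_t m = 0; m < members[c].size(); ++m) {
        R_xlen_t p = members[c][m];
        int z = (int)(p % nz);
        int y = (int)((p / nz) % ny);
        int x = (int)(p / ((R_xlen_t)nz * ny));
        const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int o = 0; o < 6; ++o) {
          int z2 = z + off[o][0], y2 = y + off[o][1], x2 = x + off[o][2];
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
          R_xlen_t q = (R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
          int cq = comp[q];
          if (cq == c || assigned[cq] < 0) continue;
          int tgt = assigned[cq];
          double d = std::fabs(my_mean - comp_sum[tgt] / comp_size[tgt]);
          int tlab = comp_label[tgt];
          if (d < best_d || (d == best_d && tlab < best_lab)) {
            best_d = d; best = tgt; best_lab = tlab;
          }
        }
      }
      if (best >= 0) {
        assigned[c] = best;
        changed = true;
      }
    }
  }

  // contiguous relabelling by increasing surviving original label
  std::vector<int> newlab(maxlab + 1, -1);
  int K = 0;
  for (int lab = 0; lab <= maxlab; ++lab)
    if (keeper[lab] >= 0) newlab[lab] = K++;
  IntegerVector out(n);
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = newlab[comp_label[assigned[comp[p]]]];
  return out;
}
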