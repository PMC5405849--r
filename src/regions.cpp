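#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static int n_offsets(int connectivity) {
  switch (connectivity) {
    case 6: return 3;
    case 18: return 9;
    case 26: return 13;
  }
  return 0;
}

// forward half of the 26-neighbourhood, ordered 6-face, 12-edge, 8-corner
static const int OFF[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {0,1,1},{0,1,-1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// Edges of the region adjacency graph of an integer partition (0-based
// labels, R column-major dim = (nz,ny,nx)). boundary_count = number of
// voxel pairs adjacent under the chosen connectivity spanning the regions.
// [[Rcpp::export]]
DataFrame cpp_region_edges(IntegerVector labels, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int noff = n_offsets(connectivity);
  if (noff == 0) stop("connectivity must be 6, 18 or 26");
  std::unordered_map<long long, long long> counts;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t p = (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        int lp = labels[p];
        for (int o = 0; o < noff; ++o) {
          int z2 = z + OFF[o][0], y2 = y + OFF[o][1], x2 = x + OFF[o][2];
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
          R_xlen_t q = (R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
          int lq = labels[q];
          if (lp == lq) continue;
          int a = std::min(lp, lq), b = std::max(lp, lq);
          counts[((long long)a << 32) | (unsigned int)b] += 1;
        }
      }
  std::vector<long long> keys;
  keys.reserve(counts.size());
  for (std::unordered_map<long long, long long>::iterator it = counts.begin();
       it != counts.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  const int m = (int)keys.size();
  IntegerVector from(m), to(m), cnt(m);
  for (int i = 0; i < m; ++i) {
    from[i] = (int)(keys[i] >> 32);
    to[i] = (int)(keys[i] & 0xffffffffLL);
    cnt[i] = (int)counts[keys[i]];
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["boundary_count"] = cnt);
}

// Connected components of a binary mask: 0 = background, components numbered
// 1..ncomp in scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_connected_components(LogicalVector mask, IntegerVector dim,
                                       int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int noff = n_offsets(connectivity);
  if (noff == 0) stop("connectivity must be 6, 18 or 26");
  IntegerVector comp(n); // zeros
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || comp[start] > 0) continue;
    ++ncomp;
    comp[start] = ncomp;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int o = 0; o < noff; ++o) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int z2 = z + sgn * OFF[o][0], y2 = y + sgn * OFF[o][1], x2 = x + sgn * OFF[o][2];
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
          R_xlen_t q = (R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
          if (mask[q] && comp[q] == 0) {
            comp[q] = ncomp;
            stack.push_back(q);
          }
        }
      }
    }
  }
  return comp;
}

// Binary dilation/erosion by an explicit offset set (rows of `offs` are
// (dz,dy,dx)). Out-of-bounds neighbours take `border_value` for erosion and
// are ignored for dilation.
// [[Rcpp::export]]
LogicalVector cpp_morph_binary(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offs, bool dilate, bool border_value) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int m = offs.nrow();
  LogicalVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t p = (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        bool res = dilate ? false : true;
        for (int o = 0; o < m; ++o) {
          int z2 = z + offs(o, 0), y2 = y + offs(o, 1), x2 = x + offs(o, 2);
          bool val;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) {
            if (dilate) continue;
            val = border_value;
          } else {
            val = mask[(R_xlen_t)z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2)];
          }
          if (dilate) { if (val) { res = true; break; } }
          else        { if (!val) { res = false; break; } }
        }
        out[p] = res;
      }
  return out;
}
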