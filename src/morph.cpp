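#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// 3-D binary morphology on (z, y, x) column-major arrays.

static void neighbour_offsets(int conn, std::vector<std::array<int,3>>& off) {
  off.clear();
  if (conn == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dz || dy || dx) off.push_back({{dz,dy,dx}});
  }
}

// Connected-component labelling; returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int conn) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbour_offsets(conn, off);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int iz = cur % nz;
      int iy = (cur / nz) % ny;
      int ix = cur / ((R_xlen_t)nz * ny);
      for (auto& d : off) {
        int z = iz + d[0], y = iy + d[1], x = ix + d[2];
        if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx) continue;
        R_xlen_t j = z + nz*(y + (R_xlen_t)ny*x);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("nlabels") = next;
  return lab;
}

// Drop connected components smaller than minVoxels (>= semantics: size ==
// minVoxels is kept).
// [[Rcpp::export]]
IntegerVector cpp_remove_small(IntegerVector mask, IntegerVector dims,
                               int minVoxels, int conn) {
  IntegerVector lab = cpp_label_components(mask, dims, conn);
  int nl = as<int>(lab.attr("nlabels"));
  std::vector<R_xlen_t> sz(nl + 1, 0);
  const R_xlen_t n = lab.size();
  for (R_xlen_t i = 0; i < n; ++i) if (lab[i]) ++sz[lab[i]];
  IntegerVector out(n, 0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i] && sz[lab[i]] >= (R_xlen_t)minVoxels) out[i] = 1;
  return out;
}

// Iterated binary dilation with the 6- or 26-neighbourhood.
// [[Rcpp::export]]
IntegerVector cpp_dilate(IntegerVector mask, IntegerVector dims,
                         int iterations, int conn) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<std::array<int,3>> off;
  neighbour_offsets(conn, off);
  IntegerVector cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    IntegerVector nxt = clone(cur);
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          R_xlen_t i = iz + nz*(iy + (R_xlen_t)ny*ix);
          if (cur[i]) continue;
          for (auto& d : off) {
            int z = iz + d[0], y = iy + d[1], x = ix + d[2];
            if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx)
              continue;
            if (cur[z + nz*(y + (R_xlen_t)ny*x)]) { nxt[i] = 1; break; }
          }
        }
    cur = nxt;
  }
  (void)n;
  return cur;
}

// Rasterize capped cylinders (tubes): a voxel is set iff its centre lies
// within `radius` of a centreline segment. segs: rows of
// (z0, y0, x0, z1, y1, x1, radius) in physical mm.
// [[Rcpp::export]]
IntegerVector cpp_rasterize_tubes(IntegerVector dims, NumericVector sp,
                                  NumericVector origin, NumericMatrix segs) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out((R_xlen_t)nz * ny * nx, 0);
  for (int s = 0; s < segs.nrow(); ++s) {
    double az = segs(s,0), ay = segs(s,1), ax = segs(s,2);
    double bz = segs(s,3), by = segs(s,4), bx = segs(s,5);
    double r  = segs(s,6);
    double lo[3] = {std::min(az,bz)-r, std::min(ay,by)-r, std::min(ax,bx)-r};
    double hi[3] = {std::max(az,bz)+r, std::max(ay,by)+r, std::max(ax,bx)+r};
    int i0[3], i1[3];
    const int nn[3] = {nz, ny, nx};
    for (int a = 0; a < 3; ++a) {
      i0[a] = std::max(0, (int)std::floor((lo[a]-origin[a])/sp[a]));
      i1[a] = std::min(nn[a]-1, (int)std::ceil((hi[a]-origin[a])/sp[a]));
    }
    double dz = bz-az, dy = by-ay, dx = bx-ax;
    double len2 = dz*dz + dy*dy + dx*dx;
    for (int ix = i0[2]; ix <= i1[2]; ++ix) {
      double px = origin[2] + ix*sp[2];
      for (int iy = i0[1]; iy <= i1[1]; ++iy) {
        double py = origin[1] + iy*sp[1];
        for (int iz = i0[0]; iz <= i1[0]; ++iz) {
          double pz = origin[0] + iz*sp[0];
          double t = 0.0;
          if (len2 > 0) {
            t = ((pz-az)*dz + (py-ay)*dy + (px-ax)*dx) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double cz = az + t*dz - pz, cy = ay + t*dy - py, cx = ax + t*dx - px;
          if (cz*cz + cy*cy + cx*cx <= r*r)
            out[iz + nz*(iy + (R_xlen_t)ny*ix)] = 1;
        }
      }
    }
  }
  return out;
}

// Rasterize spheres: rows of (z, y, x, radius) in mm (aneurysm blobs).
// [[Rcpp::export]]
IntegerVector cpp_rasterize_spheres(IntegerVector dims, NumericVector sp,
                                    NumericVector origin, NumericMatrix ctr) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector out((R_xlen_t)nz * ny * nx, 0);
  for (int s = 0; s < ctr.nrow(); ++s) {
    double cz = ctr(s,0), cy = ctr(s,1), cx = ctr(s,2), r = ctr(s,3);
    int i0[3], i1[3];
    const int nn[3] = {nz, ny, nx};
    double c[3] = {cz, cy, cx};
    for (int a = 0; a < 3; ++a) {
      i0[a] = std::max(0, (int)std::floor((c[a]-r-origin[a])/sp[a]));
      i1[a] = std::min(nn[a]-1, (int)std::ceil((c[a]+r-origin[a])/sp[a]));
    }
    for (int ix = i0[2]; ix <= i1[2]; ++ix)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int iz = i0[0]; iz <= i1[0]; ++iz) {
          double pz = origin[0]+iz*sp[0]-cz, py = origin[1]+iy*sp[1]-cy,
                 px = origin[2]+ix*sp[2]-cx;
          if (pz*pz + py*py + px*px <= r*r)
            out[iz + nz*(iy + (R_xlen_t)ny*ix)] = 1;
        }
  }
  return out;
}
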