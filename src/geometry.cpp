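#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All volumes use (slice, row, col) = (z, y, x) index order, column-major,
// so linear index = iz + nz*(iy + ny*ix). Physical coordinate of index i
// along an axis is origin + i * spacing (axes ordered z, y, x throughout).

static inline double trilinear(const double* v, int nz, int ny, int nx,
                               double z, double y, double x, double fill) {
  if (z < 0 || y < 0 || x < 0 || z > nz - 1 || y > ny - 1 || x > nx - 1)
    return fill;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
      x1 = std::min(x0 + 1, nx - 1);
  double fz = z - z0, fy = y - y0, fx = x - x0;
  #define V(a,b,c) v[(a) + nz*((b) + (R_xlen_t)ny*(c))]
  double c00 = V(z0,y0,x0)*(1-fz) + V(z1,y0,x0)*fz;
  double c01 = V(z0,y0,x1)*(1-fz) + V(z1,y0,x1)*fz;
  double c10 = V(z0,y1,x0)*(1-fz) + V(z1,y1,x0)*fz;
  double c11 = V(z0,y1,x1)*(1-fz) + V(z1,y1,x1)*fz;
  #undef V
  double c0 = c00*(1-fy) + c10*fy;
  double c1 = c01*(1-fy) + c11*fy;
  return c0*(1-fx) + c1*fx;
}

// Resample `vol` (geometry spIn/orIn) onto an output grid (dimOut/spOut/orOut)
// through the affine map q = M p + b taking output physical points p into
// input physical space. mode: 0 nearest, 1 trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dimIn,
                           IntegerVector dimOut,
                           NumericVector spOut, NumericVector orOut,
                           NumericVector spIn, NumericVector orIn,
                           NumericMatrix M, NumericVector b,
                           int mode, double fill) {
  const int nz = dimIn[0], ny = dimIn[1], nx = dimIn[2];
  const int oz = dimOut[0], oy = dimOut[1], ox = dimOut[2];
  NumericVector out((R_xlen_t)oz * oy * ox);
  const double* v = vol.begin();
  double m00=M(0,0),m01=M(0,1),m02=M(0,2),
         m10=M(1,0),m11=M(1,1),m12=M(1,2),
         m20=M(2,0),m21=M(2,1),m22=M(2,2);
  R_xlen_t idx = 0;
  for (int ix = 0; ix < ox; ++ix) {
    double px = orOut[2] + ix * spOut[2];
    for (int iy = 0; iy < oy; ++iy) {
      double py = orOut[1] + iy * spOut[1];
      for (int iz = 0; iz < oz; ++iz) {
        double pz = orOut[0] + iz * spOut[0];
        double qz = m00*pz + m01*py + m02*px + b[0];
        double qy = m10*pz + m11*py + m12*px + b[1];
        double qx = m20*pz + m21*py + m22*px + b[2];
        double gz = (qz - orIn[0]) / spIn[0];
        double gy = (qy - orIn[1]) / spIn[1];
        double gx = (qx - orIn[2]) / spIn[2];
        double val;
        if (mode == 1) {
          val = trilinear(v, nz, ny, nx, gz, gy, gx, fill);
        } else {
          long rz = std::lround(gz), ry = std::lround(gy), rx = std::lround(gx);
          if (rz < 0 || ry < 0 || rx < 0 || rz >= nz || ry >= ny || rx >= nx)
            val = fill;
          else
            val = v[rz + nz*(ry + (R_xlen_t)ny*rx)];
        }
        // column-major (z,y,x): iz fastest, then iy, then ix -- matches loop order
        out[idx++] = val;
      }
    }
  }
  // loop fills iz fastest within iy within ix but linear index must be
  // iz + oz*(iy + oy*ix); the loop nesting above does exactly that.
  return out;
}

// 2-D warp of a (H, W, C) image through in_rc = A[,1:2] %*% out_rc + A[,3]
// (row/col coordinates, 0-based). mode: 0 nearest, 1 bilinear.
// [[Rcpp::export]]
NumericVector cpp_warp2d(NumericVector img, IntegerVector dims,
                         NumericMatrix A, int mode, double fill) {
  const int H = dims[0], W = dims[1], C = dims[2];
  NumericVector out((R_xlen_t)H * W * C);
  const double* v = img.begin();
  for (int c = 0; c < C; ++c) {
    const double* pc = v + (R_xlen_t)H * W * c;
    double* oc = out.begin() + (R_xlen_t)H * W * c;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double sr = A(0,0)*h + A(0,1)*w + A(0,2);
        double sc = A(1,0)*h + A(1,1)*w + A(1,2);
        double val;
        if (mode == 1) {
          if (sr < 0 || sc < 0 || sr > H - 1 || sc > W - 1) { val = fill; }
          else {
            int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
            int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
            double fr = sr - r0, fc = sc - c0;
            val = pc[r0 + (R_xlen_t)H*c0]*(1-fr)*(1-fc)
                + pc[r1 + (R_xlen_t)H*c0]*fr*(1-fc)
                + pc[r0 + (R_xlen_t)H*c1]*(1-fr)*fc
                + pc[r1 + (R_xlen_t)H*c1]*fr*fc;
          }
        } else {
          long rr = std::lround(sr), cc = std::lround(sc);
          if (rr < 0 || cc < 0 || rr >= H || cc >= W) val = fill;
          else val = pc[rr + (R_xlen_t)H*cc];
        }
        oc[h + (R_xlen_t)H*w] = val;
      }
    }
  }
  return out;
}

// Block-mean downsampling by per-axis factors in {1,2} (registration pyramid).
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector vol, IntegerVector dims,
                              IntegerVector fac) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int fz = fac[0], fy = fac[1], fx = fac[2];
  const int oz = nz / fz, oy = ny / fy, ox = nx / fx;
  NumericVector out((R_xlen_t)oz * oy * ox);
  const double* v = vol.begin();
  R_xlen_t idx = 0;
  for (int ix = 0; ix < ox; ++ix)
    for (int iy = 0; iy < oy; ++iy)
      for (int iz = 0; iz < oz; ++iz) {
        double s = 0; int n = 0;
        for (int dx = 0; dx < fx; ++dx)
          for (int dy = 0; dy < fy; ++dy)
            for (int dz = 0; dz < fz; ++dz) {
              s += v[(iz*fz+dz) + nz*((iy*fy+dy) + (R_xlen_t)ny*(ix*fx+dx))];
              ++n;
            }
        out[idx++] = s / n;
      }
  out.attr("odim") = IntegerVector::create(oz, oy, ox);
  return out;
}

// Fused resample + normalized cross-correlation: correlates vol (moving,
// trilinearly sampled through q = M p + b) with fixVals on the fixed grid
// without materializing the resampled volume.
// [[Rcpp::export]]
double cpp_ncc_transformed(NumericVector vol, IntegerVector dimIn,
                           NumericVector fixVals, IntegerVector dimFix,
                           NumericVector spFix, NumericVector orFix,
                           NumericVector spIn, NumericVector orIn,
                           NumericMatrix M, NumericVector b, double fill) {
  const int nz = dimIn[0], ny = dimIn[1], nx = dimIn[2];
  const int oz = dimFix[0], oy = dimFix[1], ox = dimFix[2];
  const double* v = vol.begin();
  const double* f = fixVals.begin();
  double m00=M(0,0),m01=M(0,1),m02=M(0,2),
         m10=M(1,0),m11=M(1,1),m12=M(1,2),
         m20=M(2,0),m21=M(2,1),m22=M(2,2);
  double sx=0, sy=0, sxx=0, syy=0, sxy=0;
  R_xlen_t n = 0, idx = 0;
  for (int ix = 0; ix < ox; ++ix) {
    double px = orFix[2] + ix * spFix[2];
    for (int iy = 0; iy < oy; ++iy) {
      double py = orFix[1] + iy * spFix[1];
      for (int iz = 0; iz < oz; ++iz) {
        double pz = orFix[0] + iz * spFix[0];
        double gz = (m00*pz + m01*py + m02*px + b[0] - orIn[0]) / spIn[0];
        double gy = (m10*pz + m11*py + m12*px + b[1] - orIn[1]) / spIn[1];
        double gx = (m20*pz + m21*py + m22*px + b[2] - orIn[2]) / spIn[2];
        double val = trilinear(v, nz, ny, nx, gz, gy, gx, fill);
        double yv = f[idx++];
        sx += val; sy += yv; sxx += val*val; syy += yv*yv; sxy += val*yv;
        ++n;
      }
    }
  }
  double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 0 || vy <= 0) return -1.0;
  return (sxy - sx * sy / n) / std::sqrt(vx * vy);
}

// Separable Gaussian smoothing with reflective boundaries; sigma given in
// voxels per axis (0 skips an axis).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dims,
                               NumericVector sigma) {
  const int nd[3] = {dims[0], dims[1], dims[2]};
  std::vector<double> cur(vol.begin(), vol.end());
  std::vector<double> nxt(cur.size());
  const R_xlen_t strides[3] = {1, nd[0], (R_xlen_t)nd[0] * nd[1]};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(3 * s));
    std::vector<double> k(2 * rad + 1);
    double ks = 0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * i * i / (s * s));
      ks += k[i + rad];
    }
    for (auto& v : k) v /= ks;
    const int n = nd[ax];
    const R_xlen_t st = strides[ax];
    const R_xlen_t total = (R_xlen_t)nd[0] * nd[1] * nd[2];
    for (R_xlen_t base = 0; base < total; ++base) {
      // position along this axis
      const int pos = (int)((base / st) % n);
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int p = pos + i;
        if (p < 0) p = -p;                  // reflect
        if (p >= n) p = 2 * n - 2 - p;
        acc += k[i + rad] * cur[base + (R_xlen_t)(p - pos) * st];
      }
      nxt[base] = acc;
    }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  return out;
}


// Locally normalized cross-correlation between two volumes on the same
// grid: mean over voxels of the correlation computed in a box window
// (radius in voxels per axis), via 3-D summed-area tables. Windows with
// negligible variance in either image are skipped.
// [[Rcpp::export]]
double cpp_lncc(NumericVector xv, NumericVector yv, IntegerVector dims,
                IntegerVector rad) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  auto sat = [&](const double* src, std::vector<double>& t) {
    t.assign((size_t)(nz + 1) * (ny + 1) * (nx + 1), 0.0);
    const R_xlen_t sz = 1, sy2 = nz + 1, sx2 = (R_xlen_t)(nz + 1) * (ny + 1);
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          R_xlen_t o = (iz + 1) * sz + (R_xlen_t)(iy + 1) * sy2 +
                       (R_xlen_t)(ix + 1) * sx2;
          t[o] = src[iz + nz * (iy + (R_xlen_t)ny * ix)]
               + t[o - sz] + t[o - sy2] + t[o - sx2]
               - t[o - sz - sy2] - t[o - sz - sx2] - t[o - sy2 - sx2]
               + t[o - sz - sy2 - sx2];
        }
  };
  std::vector<double> x2(n), y2(n), xy(n);
  const double* px = xv.begin();
  const double* py = yv.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    x2[i] = px[i] * px[i];
    y2[i] = py[i] * py[i];
    xy[i] = px[i] * py[i];
  }
  std::vector<double> Sx, Sy, Sxx, Syy, Sxy;
  sat(px, Sx); sat(py, Sy); sat(x2.data(), Sxx);
  sat(y2.data(), Syy); sat(xy.data(), Sxy);
  const R_xlen_t sz = 1, sy2 = nz + 1, sx2 = (R_xlen_t)(nz + 1) * (ny + 1);
  auto boxsum = [&](const std::vector<double>& t, int z0, int z1, int y0,
                    int y1, int x0, int x1) {
    R_xlen_t a0 = z0 * sz, a1 = (z1 + 1) * sz;
    R_xlen_t b0 = (R_xlen_t)y0 * sy2, b1 = (R_xlen_t)(y1 + 1) * sy2;
    R_xlen_t c0 = (R_xlen_t)x0 * sx2, c1 = (R_xlen_t)(x1 + 1) * sx2;
    return t[a1 + b1 + c1] - t[a0 + b1 + c1] - t[a1 + b0 + c1]
         - t[a1 + b1 + c0] + t[a0 + b0 + c1] + t[a0 + b1 + c0]
         + t[a1 + b0 + c0] - t[a0 + b0 + c0];
  };
  double acc = 0;
  R_xlen_t m = 0;
  for (int ix = 0; ix < nx; ++ix) {
    int x0 = std::max(0, ix - rad[2]), x1 = std::min(nx - 1, ix + rad[2]);
    for (int iy = 0; iy < ny; ++iy) {
      int y0 = std::max(0, iy - rad[1]), y1 = std::min(ny - 1, iy + rad[1]);
      for (int iz = 0; iz < nz; ++iz) {
        int z0 = std::max(0, iz - rad[0]), z1 = std::min(nz - 1, iz + rad[0]);
        double w = (double)(z1 - z0 + 1) * (y1 - y0 + 1) * (x1 - x0 + 1);
        double sx = boxsum(Sx, z0, z1, y0, y1, x0, x1);
        double sy = boxsum(Sy, z0, z1, y0, y1, x0, x1);
        double vx = boxsum(Sxx, z0, z1, y0, y1, x0, x1) - sx * sx / w;
        double vy = boxsum(Syy, z0, z1, y0, y1, x0, x1) - sy * sy / w;
        if (vx < 1e-6 * w || vy < 1e-6 * w) continue;
        double cv = boxsum(Sxy, z0, z1, y0, y1, x0, x1) - sx * sy / w;
        acc += cv / std::sqrt(vx * vy);
        ++m;
      }
    }
  }
  return m > 0 ? acc / m : -1.0;
}
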