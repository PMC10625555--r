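// Affine resampling of 3D scalar grids: every output voxel index o (0-based)
// is mapped to input voxel coordinates p = A %*% o + t, then sampled with
// trilinear interpolation or nearest neighbour. Out-of-bounds samples take
// the fill value.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_affine_resample(const arma::vec& x, IntegerVector dims,
                                  IntegerVector outdims, const arma::mat& A,
                                  const arma::vec& t, int nearest,
                                  double fill, int clamp = 0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* xp = x.memptr();
  R_xlen_t l = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++l) {
        double px = A(0,0)*i + A(0,1)*j + A(0,2)*k + t[0];
        double py = A(1,0)*i + A(1,1)*j + A(1,2)*k + t[1];
        double pz = A(2,0)*i + A(2,1)*j + A(2,2)*k + t[2];
        if (clamp) {  // border-replicate (resampling); otherwise fill (rotation)
          px = std::min(std::max(px, 0.0), (double)nx - 1);
          py = std::min(std::max(py, 0.0), (double)ny - 1);
          pz = std::min(std::max(pz, 0.0), (double)nz - 1);
        }
        if (nearest) {
          const int ix = (int)std::lround(px);
          const int iy = (int)std::lround(py);
          const int iz = (int)std::lround(pz);
          if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
            out[l] = fill;
          } else {
            out[l] = xp[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
          }
        } else {
          const int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
          if (x0 < -1 || x0 >= nx || y0 < -1 || y0 >= ny || z0 < -1 || z0 >= nz) {
            out[l] = fill;
            continue;
          }
          const double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz) {
            const int zz = z0 + dz;
            const double wz = dz ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int yy = y0 + dy;
              const double wy = dy ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int dx = 0; dx < 2; ++dx) {
                const int xx = x0 + dx;
                const double wx = dx ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                double v;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) {
                  v = fill;
                } else {
                  v = xp[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
                }
                acc += wx * wy * wz * v;
              }
            }
          }
          out[l] = acc;
        }
      }
    }
  }
  out.attr("dim") = outdims;
  return out;
}

// Minimal Euclidean distance from every row of a (n x 3) to the point set b
// (m x 3). Distances in voxel units; used for Hausdorff metrics.
// [[Rcpp::export]]
NumericVector cpp_directed_min_dist(const arma::mat& a, const arma::mat& b) {
  const arma::uword n = a.n_rows, m = b.n_rows;
  NumericVector res(n);
  for (arma::uword i = 0; i < n; ++i) {
    const double ax = a(i,0), ay = a(i,1), az = a(i,2);
    double best = R_PosInf;
    for (arma::uword j = 0; j < m; ++j) {
      const double dx = ax - b(j,0), dy = ay - b(j,1), dz = az - b(j,2);
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    res[i] = std::sqrt(best);
  }
  return res;
}

// Stamp unit-radius-scaled balls onto a voxel grid: for each centre row of
// pts (k x 3, 0-based voxel coordinates) set mask voxels within radius r to 1.
// Used by the phantom rasteriser.
// [[Rcpp::export]]
IntegerVector cpp_stamp_balls(IntegerVector mask, IntegerVector dims,
                              const arma::mat& pts, double r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(mask);
  const int ir = (int)std::ceil(r);
  const double r2 = r * r;
  for (arma::uword p = 0; p < pts.n_rows; ++p) {
    const double cx = pts(p,0), cy = pts(p,1), cz = pts(p,2);
    const int x0 = std::max(0, (int)std::floor(cx - ir));
    const int x1 = std::min(nx - 1, (int)std::ceil(cx + ir));
    const int y0 = std::max(0, (int)std::floor(cy - ir));
    const int y1 = std::min(ny - 1, (int)std::ceil(cy + ir));
    const int z0 = std::max(0, (int)std::floor(cz - ir));
    const int z1 = std::min(nz - 1, (int)std::ceil(cz + ir));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          const double dx = x - cx, dy = y - cy, dz = z - cz;
          if (dx*dx + dy*dy + dz*dz <= r2)
            out[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = 1;
        }
  }
  return out;
}
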