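// GEMM-based 3D convolution kernels for the volumetric network engine.
// Array layout is column-major with dimensions (channels, x, y, z), matching
// R arrays of dim c(C, nx, ny, nz). All convolutions are isotropic (cubic
// kernel, same stride/padding per axis).
//
// The unfolded ("im2col") matrix is never materialised in full: unfolding is
// tiled over z-planes of the output and each tile (L_tile x C*k^3, with the
// x-run of output voxels contiguous) is consumed by a GEMM while it is still
// cache-resident. This keeps the kernels compute-bound; a full unfold of a
// 32-channel 128^3 volume would otherwise stream hundreds of MB through
// memory per convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static arma::mat& tile_buffer() {
  static arma::mat buf;
  return buf;
}

// number of output z-planes per tile, aiming at ~4 MB tiles
static int planes_per_tile(int ox, int oy, int oz, arma::uword CK) {
  double per_plane = (double)CK * ox * oy * 8.0;
  int p = (int)std::max(1.0, std::floor(4.0e6 / per_plane));
  return std::min(p, oz);
}

// Unfold output z-planes [z0, z1) of x into cols (Ltile x C*k^3); column
// layout has the output x-run contiguous.
static void im2col_tile(const double* xp, int C, int nx, int ny, int nz,
                        int k, int stride, int pad, int z0, int z1,
                        arma::mat& cols) {
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const arma::uword Lt = (arma::uword)ox * oy * (z1 - z0);
  cols.set_size(Lt, (arma::uword)C * k * k * k);
  for (int kz = 0; kz < k; ++kz)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        int xo_lo = std::max(0, (pad - kx + stride - 1) / stride);
        int xo_hi = std::min(ox, (nx - 1 - kx + pad) / stride + 1);
        if (xo_hi < xo_lo) xo_hi = xo_lo;
        for (int c = 0; c < C; ++c) {
          const arma::uword row = (arma::uword)c +
            (arma::uword)C * (kx + k * (ky + k * kz));
          double* dst0 = cols.colptr(row);
          for (int z = z0; z < z1; ++z) {
            const int iz = z * stride + kz - pad;
            const bool z_ok = iz >= 0 && iz < nz;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky - pad;
              double* dst = dst0 + (arma::uword)ox * (y + (arma::uword)oy * (z - z0));
              if (!z_ok || iy < 0 || iy >= ny) {
                std::fill(dst, dst + ox, 0.0);
                continue;
              }
              std::fill(dst, dst + xo_lo, 0.0);
              std::fill(dst + xo_hi, dst + ox, 0.0);
              const double* src = xp + (arma::uword)c +
                (arma::uword)C * ((arma::uword)(xo_lo * stride + kx - pad) +
                                  (arma::uword)nx * (iy + (arma::uword)ny * iz));
              const arma::uword sstep = (arma::uword)C * stride;
              for (int xo = xo_lo; xo < xo_hi; ++xo, src += sstep)
                dst[xo] = *src;
            }
          }
        }
      }
}

// Adjoint: scatter-add cols (Ltile x C*k^3) for output z-planes [z0, z1)
// back onto the (C, nx, ny, nz) grid.
static void col2im_tile(const arma::mat& cols, int C, int nx, int ny, int nz,
                        int k, int stride, int pad, int z0, int z1,
                        double* xp) {
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  for (int kz = 0; kz < k; ++kz)
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        int xo_lo = std::max(0, (pad - kx + stride - 1) / stride);
        int xo_hi = std::min(ox, (nx - 1 - kx + pad) / stride + 1);
        if (xo_hi < xo_lo) xo_hi = xo_lo;
        for (int c = 0; c < C; ++c) {
          const arma::uword row = (arma::uword)c +
            (arma::uword)C * (kx + k * (ky + k * kz));
          const double* src0 = cols.colptr(row);
          for (int z = z0; z < z1; ++z) {
            const int iz = z * stride + kz - pad;
            if (iz < 0 || iz >= nz) continue;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride + ky - pad;
              if (iy < 0 || iy >= ny) continue;
              const double* src = src0 + (arma::uword)ox * (y + (arma::uword)oy * (z - z0));
              double* dst = xp + (arma::uword)c +
                (arma::uword)C * ((arma::uword)(xo_lo * stride + kx - pad) +
                                  (arma::uword)nx * (iy + (arma::uword)ny * iz));
              const arma::uword dstep = (arma::uword)C * stride;
              for (int xo = xo_lo; xo < xo_hi; ++xo, dst += dstep)
                *dst += src[xo];
            }
          }
        }
      }
}

// Forward convolution. w is (oc) x (ic*k^3); b has length oc.
// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(const NumericVector& x, IntegerVector dims,
                                 const arma::mat& w, const arma::vec& b,
                                 int k, int stride, int pad) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  const int oc = w.n_rows;
  NumericVector res((R_xlen_t)oc * ox * oy * oz);
  res.attr("dim") = IntegerVector::create(oc, ox, oy, oz);
  arma::mat out(res.begin(), oc, (arma::uword)ox * oy * oz, false, true);
  arma::mat& cols = tile_buffer();
  const int pt = planes_per_tile(ox, oy, oz, w.n_cols);
  for (int z0 = 0; z0 < oz; z0 += pt) {
    const int z1 = std::min(oz, z0 + pt);
    im2col_tile(x.begin(), C, nx, ny, nz, k, stride, pad, z0, z1, cols);
    out.cols((arma::uword)ox * oy * z0, (arma::uword)ox * oy * z1 - 1) =
      w * cols.t();
  }
  out.each_col() += b;
  return res;
}

// Backward convolution: gradients w.r.t. input, weights and bias.
// gout is the gradient at the output, shaped (oc, ox, oy, oz).
// need_dx = 0 skips the input gradient (constant leaf below).
// [[Rcpp::export]]
List cpp_conv3d_backward(const NumericVector& x, IntegerVector dims,
                         const arma::mat& w, const NumericVector& gout,
                         int k, int stride, int pad, int need_dx) {
  const int C = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const int ox = out_dim(nx, k, stride, pad);
  const int oy = out_dim(ny, k, stride, pad);
  const int oz = out_dim(nz, k, stride, pad);
  const int oc = w.n_rows;
  const arma::mat gmat(const_cast<double*>(gout.begin()), oc,
                       (arma::uword)ox * oy * oz, false, true);
  arma::mat dw(oc, w.n_cols, arma::fill::zeros);
  arma::vec db = arma::sum(gmat, 1);
  NumericVector dxr;
  double* dxp = nullptr;
  if (need_dx) {
    dxr = NumericVector((R_xlen_t)C * nx * ny * nz);
    dxr.attr("dim") = dims;
    dxp = dxr.begin();
  }
  arma::mat& cols = tile_buffer();
  const int pt = planes_per_tile(ox, oy, oz, w.n_cols);
  for (int z0 = 0; z0 < oz; z0 += pt) {
    const int z1 = std::min(oz, z0 + pt);
    const arma::mat gt = gmat.cols((arma::uword)ox * oy * z0,
                                   (arma::uword)ox * oy * z1 - 1);
    im2col_tile(x.begin(), C, nx, ny, nz, k, stride, pad, z0, z1, cols);
    dw += gt * cols;
    if (need_dx) {
      cols = gt.t() * w;               // reuse buffer for dcols tile
      col2im_tile(cols, C, nx, ny, nz, k, stride, pad, z0, z1, dxp);
    }
  }
  return List::create(_["dx"] = dxr, _["dw"] = dw, _["db"] = db);
}

// Forward transposed convolution (kernel k, stride k, no padding): the
// adjoint of a stride-k convolution, used for decoder upsampling. w is
// (ic) x (oc*k^3) so the layer maps ic -> oc channels and multiplies the
// spatial dims by k. Tiled over input z-planes.
// [[Rcpp::export]]
NumericVector cpp_tconv3d_forward(const NumericVector& x, IntegerVector dims,
                                  const arma::mat& w, const arma::vec& b,
                                  int k) {
  const int ic = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const int oc = w.n_cols / (k * k * k);
  NumericVector res((R_xlen_t)oc * nx * k * ny * k * nz * k);
  res.attr("dim") = IntegerVector::create(oc, nx * k, ny * k, nz * k);
  std::fill(res.begin(), res.end(), 0.0);
  const arma::mat xmat(const_cast<double*>(x.begin()), ic,
                       (arma::uword)nx * ny * nz, false, true);
  arma::mat& cols = tile_buffer();
  const int pt = planes_per_tile(nx, ny, nz, w.n_cols);
  for (int z0 = 0; z0 < nz; z0 += pt) {
    const int z1 = std::min(nz, z0 + pt);
    cols = xmat.cols((arma::uword)nx * ny * z0,
                     (arma::uword)nx * ny * z1 - 1).t() * w;  // Lt x (oc*k^3)
    // scatter into the output grid: input plane z covers output planes k*z..k*z+k-1
    col2im_tile(cols, oc, nx * k, ny * k, nz * k, k, k, 0, z0, z1, res.begin());
  }
  double* op = res.begin();
  const arma::uword V = (arma::uword)nx * k * ny * k * nz * k;
  for (arma::uword v = 0; v < V; ++v)
    for (int c = 0; c < oc; ++c) op[(arma::uword)oc * v + c] += b[c];
  return res;
}

// [[Rcpp::export]]
List cpp_tconv3d_backward(const NumericVector& x, IntegerVector dims,
                          const arma::mat& w, const NumericVector& gout,
                          int k) {
  const int ic = dims[0], nx = dims[1], ny = dims[2], nz = dims[3];
  const int oc = w.n_cols / (k * k * k);
  const arma::mat xmat(const_cast<double*>(x.begin()), ic,
                       (arma::uword)nx * ny * nz, false, true);
  NumericVector dxr((R_xlen_t)ic * nx * ny * nz);
  dxr.attr("dim") = dims;
  arma::mat dx(dxr.begin(), ic, (arma::uword)nx * ny * nz, false, true);
  arma::mat dw(ic, w.n_cols, arma::fill::zeros);
  arma::mat& gcols = tile_buffer();
  const int pt = planes_per_tile(nx, ny, nz, w.n_cols);
  for (int z0 = 0; z0 < nz; z0 += pt) {
    const int z1 = std::min(nz, z0 + pt);
    im2col_tile(gout.begin(), oc, nx * k, ny * k, nz * k, k, k, 0, z0, z1, gcols);
    const arma::uword c0 = (arma::uword)nx * ny * z0;
    const arma::uword c1 = (arma::uword)nx * ny * z1 - 1;
    dx.cols(c0, c1) = w * gcols.t();
    dw += xmat.cols(c0, c1) * gcols;
  }
  arma::vec db(oc, arma::fill::zeros);
  const double* gp = gout.begin();
  const arma::uword V = (arma::uword)nx * k * ny * k * nz * k;
  for (arma::uword v = 0; v < V; ++v)
    for (int c = 0; c < oc; ++c) db[c] += gp[(arma::uword)oc * v + c];
  NumericVector dwr(dw.begin(), dw.end());
  dwr.attr("dim") = IntegerVector::create(dw.n_rows, dw.n_cols);
  return List::create(_["dx"] = dxr, _["dw"] = dwr, _["db"] = db);
}
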