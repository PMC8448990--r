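// Compiled numerical kernels: 3D convolution (im2col + GEMM) with input and
// weight gradients, 3D max pooling, tube rasterization against a polyline,
// and nearest-neighbour set distances for the surface metrics.
//
// Tensor layout throughout: channel-fastest 5D arrays (C, D, H, W, N) so that
// one im2col column is a run of contiguous channel blocks and the GEMM output
// writes straight into the output array's memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

constexpr int COL_BLOCK = 4096;  // im2col columns per GEMM chunk (bounds memory)

struct ConvGeom {
  int C, D, H, W;          // input
  int kd, kh, kw;          // kernel
  int sd, sh, sw;          // stride
  int pd, ph, pw;          // zero padding
  int Do, Ho, Wo;          // output spatial dims
  int K;                   // im2col rows = C*kd*kh*kw
  long nvox;               // output voxels per sample
};

ConvGeom make_geom(const IntegerVector& xdim, const IntegerVector& k,
                   const IntegerVector& s, const IntegerVector& p) {
  ConvGeom g;
  g.C = xdim[0]; g.D = xdim[1]; g.H = xdim[2]; g.W = xdim[3];
  g.kd = k[0]; g.kh = k[1]; g.kw = k[2];
  g.sd = s[0]; g.sh = s[1]; g.sw = s[2];
  g.pd = p[0]; g.ph = p[1]; g.pw = p[2];
  g.Do = (g.D + 2 * g.pd - g.kd) / g.sd + 1;
  g.Ho = (g.H + 2 * g.ph - g.kh) / g.sh + 1;
  g.Wo = (g.W + 2 * g.pw - g.kw) / g.sw + 1;
  g.K = g.C * g.kd * g.kh * g.kw;
  g.nvox = (long)g.Do * g.Ho * g.Wo;
  return g;
}

// Fill col (K x nb) with input patches for output voxels [j0, j0+nb).
void im2col_block(const double* xs, const ConvGeom& g, long j0, int nb,
                  arma::mat& col) {
  const long planeDH = (long)g.D * g.H;
  for (int b = 0; b < nb; ++b) {
    long j = j0 + b;
    int od = (int)(j % g.Do);
    int oh = (int)((j / g.Do) % g.Ho);
    int ow = (int)(j / ((long)g.Do * g.Ho));
    int d0 = od * g.sd - g.pd;
    int h0 = oh * g.sh - g.ph;
    int w0 = ow * g.sw - g.pw;
    double* cp = col.colptr(b);
    for (int cw = 0; cw < g.kw; ++cw) {
      int w = w0 + cw;
      for (int ch = 0; ch < g.kh; ++ch) {
        int h = h0 + ch;
        for (int cd = 0; cd < g.kd; ++cd) {
          int d = d0 + cd;
          if (d >= 0 && d < g.D && h >= 0 && h < g.H && w >= 0 && w < g.W) {
            const double* src = xs + (size_t)g.C * (d + (long)g.D * h + planeDH * w);
            std::copy(src, src + g.C, cp);
          } else {
            std::fill(cp, cp + g.C, 0.0);
          }
          cp += g.C;
        }
      }
    }
  }
}

// Scatter-add col (K x nb) back into gx for output voxels [j0, j0+nb).
void col2im_block(double* gxs, const ConvGeom& g, long j0, int nb,
                  const arma::mat& col) {
  const long planeDH = (long)g.D * g.H;
  for (int b = 0; b < nb; ++b) {
    long j = j0 + b;
    int od = (int)(j % g.Do);
    int oh = (int)((j / g.Do) % g.Ho);
    int ow = (int)(j / ((long)g.Do * g.Ho));
    int d0 = od * g.sd - g.pd;
    int h0 = oh * g.sh - g.ph;
    int w0 = ow * g.sw - g.pw;
    const double* cp = col.colptr(b);
    for (int cw = 0; cw < g.kw; ++cw) {
      int w = w0 + cw;
      for (int ch = 0; ch < g.kh; ++ch) {
        int h = h0 + ch;
        for (int cd = 0; cd < g.kd; ++cd) {
          int d = d0 + cd;
          if (d >= 0 && d < g.D && h >= 0 && h < g.H && w >= 0 && w < g.W) {
            double* dst = gxs + (size_t)g.C * (d + (long)g.D * h + planeDH * w);
            for (int c = 0; c < g.C; ++c) dst[c] += cp[c];
          }
          cp += g.C;
        }
      }
    }
  }
}

}  // namespace

// x: (C,D,H,W,N); w: K x Cout with K = C*kd*kh*kw (channel fastest, then kd,kh,kw)
// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(const NumericVector& x, const arma::mat& w,
                                 IntegerVector xdim, int n_batch,
                                 IntegerVector kernel, IntegerVector stride,
                                 IntegerVector pad) {
  ConvGeom g = make_geom(xdim, kernel, stride, pad);
  const int Cout = (int)w.n_cols;
  if ((int)w.n_rows != g.K) stop("conv weight rows != C*kd*kh*kw");
  NumericVector y(Rcpp::no_init((R_xlen_t)Cout * g.nvox * n_batch));
  y.attr("dim") = IntegerVector::create(Cout, g.Do, g.Ho, g.Wo, n_batch);
  arma::mat wt = w.t();  // Cout x K
  arma::mat col(g.K, COL_BLOCK);
  const size_t xstep = (size_t)g.C * g.D * g.H * g.W;
  const size_t ystep = (size_t)Cout * g.nvox;
  for (int n = 0; n < n_batch; ++n) {
    const double* xs = x.begin() + n * xstep;
    double* ys = REAL(y) + n * ystep;
    for (long j0 = 0; j0 < g.nvox; j0 += COL_BLOCK) {
      int nb = (int)std::min((long)COL_BLOCK, g.nvox - j0);
      im2col_block(xs, g, j0, nb, col);
      arma::mat out(ys + (size_t)Cout * j0, Cout, nb, false, true);
      out = wt * col.cols(0, nb - 1);
    }
  }
  return y;
}

// gy: (Cout,Do,Ho,Wo,N) -> gx: (C,D,H,W,N)
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(const NumericVector& gy, const arma::mat& w,
                                   IntegerVector xdim, int n_batch,
                                   IntegerVector kernel, IntegerVector stride,
                                   IntegerVector pad) {
  ConvGeom g = make_geom(xdim, kernel, stride, pad);
  const int Cout = (int)w.n_cols;
  NumericVector gx((R_xlen_t)g.C * g.D * g.H * g.W * n_batch);  // zeroed
  gx.attr("dim") = IntegerVector::create(g.C, g.D, g.H, g.W, n_batch);
  arma::mat gcol(g.K, COL_BLOCK);
  const size_t xstep = (size_t)g.C * g.D * g.H * g.W;
  const size_t ystep = (size_t)Cout * g.nvox;
  for (int n = 0; n < n_batch; ++n) {
    const double* gys = gy.begin() + n * ystep;
    double* gxs = REAL(gx) + n * xstep;
    for (long j0 = 0; j0 < g.nvox; j0 += COL_BLOCK) {
      int nb = (int)std::min((long)COL_BLOCK, g.nvox - j0);
      arma::mat gyb(const_cast<double*>(gys + (size_t)Cout * j0), Cout, nb, false, true);
      gcol.cols(0, nb - 1) = w * gyb;
      col2im_block(gxs, g, j0, nb, gcol);
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_bwd_weight(const NumericVector& x, const NumericVector& gy,
                                int cout, IntegerVector xdim, int n_batch,
                                IntegerVector kernel, IntegerVector stride,
                                IntegerVector pad) {
  ConvGeom g = make_geom(xdim, kernel, stride, pad);
  arma::mat gw(g.K, cout, arma::fill::zeros);
  arma::mat col(g.K, COL_BLOCK);
  const size_t xstep = (size_t)g.C * g.D * g.H * g.W;
  const size_t ystep = (size_t)cout * g.nvox;
  for (int n = 0; n < n_batch; ++n) {
    const double* xs = x.begin() + n * xstep;
    const double* gys = gy.begin() + n * ystep;
    for (long j0 = 0; j0 < g.nvox; j0 += COL_BLOCK) {
      int nb = (int)std::min((long)COL_BLOCK, g.nvox - j0);
      im2col_block(xs, g, j0, nb, col);
      arma::mat gyb(const_cast<double*>(gys + (size_t)cout * j0), cout, nb, false, true);
      gw += col.cols(0, nb - 1) * gyb.t();
    }
  }
  return gw;
}

// Max pooling, no padding; input dims assumed divisible as used by the network.
// Returns y and 0-based argmax offsets within each sample's (C,D,H,W) block.
// [[Rcpp::export]]
List cpp_maxpool3d_forward(const NumericVector& x, IntegerVector xdim, int n_batch,
                           IntegerVector kernel, IntegerVector stride) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int Do = (D - kd) / sd + 1, Ho = (H - kh) / sh + 1, Wo = (W - kw) / sw + 1;
  const size_t xstep = (size_t)C * D * H * W;
  const size_t ystep = (size_t)C * Do * Ho * Wo;
  NumericVector y(Rcpp::no_init((R_xlen_t)(ystep * n_batch)));
  NumericVector idx(Rcpp::no_init((R_xlen_t)(ystep * n_batch)));
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, n_batch);
  for (int n = 0; n < n_batch; ++n) {
    const double* xs = x.begin() + n * xstep;
    double* ys = REAL(y) + n * ystep;
    double* is = REAL(idx) + n * ystep;
    size_t o = 0;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh)
        for (int od = 0; od < Do; ++od)
          for (int c = 0; c < C; ++c, ++o) {
            double best = -INFINITY; size_t besti = 0;
            for (int cw = 0; cw < kw; ++cw)
              for (int ch = 0; ch < kh; ++ch)
                for (int cd = 0; cd < kd; ++cd) {
                  size_t ii = c + (size_t)C * ((od * sd + cd) +
                              (size_t)D * ((oh * sh + ch) + (size_t)H * (ow * sw + cw)));
                  if (xs[ii] > best) { best = xs[ii]; besti = ii; }
                }
            ys[o] = best; is[o] = (double)besti;
          }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_backward(const NumericVector& gy, const NumericVector& idx,
                                     IntegerVector xdim, int n_batch) {
  const size_t xstep = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx((R_xlen_t)(xstep * n_batch));
  gx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2], xdim[3], n_batch);
  const size_t ystep = (size_t)gy.size() / n_batch;
  for (int n = 0; n < n_batch; ++n) {
    const double* gys = gy.begin() + n * ystep;
    const double* is = idx.begin() + n * ystep;
    double* gxs = REAL(gx) + n * xstep;
    for (size_t o = 0; o < ystep; ++o) gxs[(size_t)is[o]] += gys[o];
  }
  return gx;
}

// Mark voxels whose center lies within `radius` (mm) of the polyline through
// `pts` (rows = points in mm, columns = d,h,w). Single-row input is a point.
// Voxel center (0-based index i) sits at (i + 0.5) * spacing.
// [[Rcpp::export]]
LogicalVector cpp_rasterize_tube(const arma::mat& pts, double radius,
                                 IntegerVector dim, NumericVector spacing) {
  const int D = dim[0], H = dim[1], W = dim[2];
  LogicalVector mask((R_xlen_t)D * H * W);  // FALSE
  mask.attr("dim") = dim;
  const double sd = spacing[0], sh = spacing[1], sw = spacing[2];
  const int nseg = pts.n_rows == 1 ? 1 : (int)pts.n_rows - 1;
  const double r2 = radius * radius;
  for (int s = 0; s < nseg; ++s) {
    arma::rowvec a = pts.row(s);
    arma::rowvec b = pts.row(pts.n_rows == 1 ? s : s + 1);
    arma::rowvec lo = arma::min(a, b), hi = arma::max(a, b);
    int d0 = std::max(0, (int)std::floor((lo[0] - radius) / sd - 0.5));
    int d1 = std::min(D - 1, (int)std::ceil((hi[0] + radius) / sd - 0.5));
    int h0 = std::max(0, (int)std::floor((lo[1] - radius) / sh - 0.5));
    int h1 = std::min(H - 1, (int)std::ceil((hi[1] + radius) / sh - 0.5));
    int w0 = std::max(0, (int)std::floor((lo[2] - radius) / sw - 0.5));
    int w1 = std::min(W - 1, (int)std::ceil((hi[2] + radius) / sw - 0.5));
    arma::rowvec ab = b - a;
    double ab2 = arma::dot(ab, ab);
    for (int w = w0; w <= w1; ++w)
      for (int h = h0; h <= h1; ++h)
        for (int d = d0; d <= d1; ++d) {
          arma::rowvec v = {(d + 0.5) * sd - a[0], (h + 0.5) * sh - a[1],
                            (w + 0.5) * sw - a[2]};
          double t = ab2 > 0 ? std::max(0.0, std::min(1.0, arma::dot(v, ab) / ab2)) : 0.0;
          arma::rowvec diff = v - t * ab;
          if (arma::dot(diff, diff) <= r2)
            mask[d + (size_t)D * (h + (size_t)H * w)] = TRUE;
        }
  }
  return mask;
}

// Mean over rows of A of the distance to the nearest row of B (coordinates
// already scaled to mm). Brute force; the masks in play are small or sparse.
// [[Rcpp::export]]
double cpp_nn_mean_dist(const arma::mat& A, const arma::mat& B) {
  const int n = A.n_rows, m = B.n_rows;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    double best = INFINITY;
    for (int j = 0; j < m; ++j) {
      double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      double dd = d0 * d0 + d1 * d1 + d2 * d2;
      if (dd < best) best = dd;
    }
    acc += std::sqrt(best);
  }
  return acc / n;
}
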