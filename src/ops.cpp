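// Low-level volumetric layer kernels.
//
// All activation tensors are R arrays with dim (C, D, H, W), column-major,
// i.e. linear index = c + C*(d + D*(h + H*w)).  Batch size is always 1
// (the training protocol uses batch_size = 1), so no batch axis is carried.
//
// Convolutions are realized as im2col + BLAS (through Armadillo, which maps
// onto R's BLAS).  To keep peak memory bounded for full-resolution volumes
// the column matrix is built for slabs of output w-slices at a time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int slab_width(int K, int D, int H, int W) {
  // target <= ~32 MB per column slab
  double per_slice = (double)K * D * H * 8.0;
  int wb = (int)std::floor(32.0 * 1024 * 1024 / std::max(per_slice, 1.0));
  if (wb < 1) wb = 1;
  if (wb > W) wb = W;
  return wb;
}

// Fill col (K x m) for output positions w in [w0, w0+wb).
// Row layout: ci + C*(od + k*(oh + k*ow)), offsets od,oh,ow in [0,k).
static void im2col_slab(const double* x, int C, int D, int H, int W,
                        int k, int pad, int w0, int wb, arma::mat& col) {
  const int K = C * k * k * k;
  col.set_size(K, (arma::uword)D * H * wb);
  col.zeros();
  for (int wi = 0; wi < wb; ++wi) {
    int w = w0 + wi;
    for (int ow = 0; ow < k; ++ow) {
      int sw = w + ow - pad;
      if (sw < 0 || sw >= W) continue;
      for (int h = 0; h < H; ++h) {
        for (int oh = 0; oh < k; ++oh) {
          int sh = h + oh - pad;
          if (sh < 0 || sh >= H) continue;
          for (int d = 0; d < D; ++d) {
            arma::uword cidx = (arma::uword)d + (arma::uword)D * (h + (arma::uword)H * wi);
            for (int od = 0; od < k; ++od) {
              int sd = d + od - pad;
              if (sd < 0 || sd >= D) continue;
              const double* src = x + (arma::uword)C * (sd + (arma::uword)D * (sh + (arma::uword)H * sw));
              double* dst = col.colptr(cidx) + C * (od + k * (oh + k * ow));
              std::memcpy(dst, src, C * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Scatter-add of a column slab back into gx (adjoint of im2col_slab).
static void col2im_slab(const arma::mat& col, double* gx, int C, int D, int H,
                        int W, int k, int pad, int w0, int wb) {
  for (int wi = 0; wi < wb; ++wi) {
    int w = w0 + wi;
    for (int ow = 0; ow < k; ++ow) {
      int sw = w + ow - pad;
      if (sw < 0 || sw >= W) continue;
      for (int h = 0; h < H; ++h) {
        for (int oh = 0; oh < k; ++oh) {
          int sh = h + oh - pad;
          if (sh < 0 || sh >= H) continue;
          for (int d = 0; d < D; ++d) {
            arma::uword cidx = (arma::uword)d + (arma::uword)D * (h + (arma::uword)H * wi);
            for (int od = 0; od < k; ++od) {
              int sd = d + od - pad;
              if (sd < 0 || sd >= D) continue;
              double* dst = gx + (arma::uword)C * (sd + (arma::uword)D * (sh + (arma::uword)H * sw));
              const double* src = col.colptr(cidx) + C * (od + k * (oh + k * ow));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix wmat,
                             NumericVector bias, int k) {
  IntegerVector dm = x.attr("dim");
  int C = dm[0], D = dm[1], H = dm[2], W = dm[3];
  int Cout = wmat.nrow();
  int K = wmat.ncol();
  if (K != C * k * k * k) stop("weight matrix does not match input channels/kernel");
  int pad = (k - 1) / 2;
  NumericVector out((R_xlen_t)Cout * D * H * W);
  out.attr("dim") = IntegerVector::create(Cout, D, H, W);
  arma::mat Wm(wmat.begin(), Cout, K, false);
  arma::vec b(bias.begin(), Cout, false);
  int wb = slab_width(K, D, H, W);
  arma::mat col;
  for (int w0 = 0; w0 < W; w0 += wb) {
    int bw = std::min(wb, W - w0);
    im2col_slab(x.begin(), C, D, H, W, k, pad, w0, bw, col);
    arma::mat o = Wm * col;            // Cout x (D*H*bw)
    o.each_col() += b;
    std::memcpy(out.begin() + (R_xlen_t)Cout * D * H * w0, o.memptr(),
                o.n_elem * sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix wmat, NumericVector gout,
                    int k) {
  IntegerVector dm = x.attr("dim");
  int C = dm[0], D = dm[1], H = dm[2], W = dm[3];
  int Cout = wmat.nrow();
  int K = wmat.ncol();
  int pad = (k - 1) / 2;
  arma::mat Wm(wmat.begin(), Cout, K, false);

  NumericVector gx((R_xlen_t)C * D * H * W);
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  arma::mat gW(Cout, K, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  int wb = slab_width(K, D, H, W);
  arma::mat col;
  for (int w0 = 0; w0 < W; w0 += wb) {
    int bw = std::min(wb, W - w0);
    im2col_slab(x.begin(), C, D, H, W, k, pad, w0, bw, col);
    arma::mat go(const_cast<double*>(gout.begin()) + (R_xlen_t)Cout * D * H * w0,
                 Cout, (arma::uword)D * H * bw, false);
    gW += go * col.t();
    gb += arma::sum(go, 1);
    arma::mat gcol = Wm.t() * go;      // K x m
    col2im_slab(gcol, gx.begin(), C, D, H, W, k, pad, w0, bw);
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(Cout, K, gW.memptr()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2x2 max pooling, stride 2.  Returns pooled output and the 1-based linear
// argmax index into the input (first maximum wins: deterministic).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int C = dm[0], D = dm[1], H = dm[2], W = dm[3];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)C * Do * Ho * Wo);
  IntegerVector idx((R_xlen_t)C * Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  idx.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  const double* xp = x.begin();
  R_xlen_t o = 0;
  for (int w = 0; w < Wo; ++w)
    for (int h = 0; h < Ho; ++h)
      for (int d = 0; d < Do; ++d)
        for (int c = 0; c < C; ++c, ++o) {
          double best = -INFINITY; R_xlen_t bi = -1;
          for (int ow = 0; ow < 2; ++ow)
            for (int oh = 0; oh < 2; ++oh)
              for (int od = 0; od < 2; ++od) {
                R_xlen_t i = c + (R_xlen_t)C * ((2 * d + od) +
                             (R_xlen_t)D * ((2 * h + oh) + (R_xlen_t)H * (2 * w + ow)));
                if (xp[i] > best) { best = xp[i]; bi = i; }
              }
          out[o] = best;
          idx[o] = (int)(bi + 1);
        }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gout, IntegerVector idx,
                               IntegerVector in_dim) {
  R_xlen_t n = (R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  for (R_xlen_t o = 0; o < gout.size(); ++o) gx[idx[o] - 1] += gout[o];
  return gx;
}

struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> w1;
};

// align-corners linear mapping n_in -> n_out
static AxisMap axis_map(int n_in, int n_out) {
  AxisMap m;
  m.i0.resize(n_out); m.i1.resize(n_out); m.w1.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (n_out == 1) ? (n_in - 1) / 2.0
                            : (double)i * (n_in - 1) / (n_out - 1);
    int i0 = (int)std::floor(s);
    if (i0 > n_in - 1) i0 = n_in - 1;
    int i1 = std::min(i0 + 1, n_in - 1);
    m.i0[i] = i0; m.i1[i] = i1; m.w1[i] = s - i0;
  }
  return m;
}

// Trilinear resize of a (C,D,H,W) tensor to (C,Do,Ho,Wo), align-corners.
// [[Rcpp::export]]
NumericVector cpp_trilinear_fwd(NumericVector x, IntegerVector out_dhw) {
  IntegerVector dm = x.attr("dim");
  int C = dm[0], D = dm[1], H = dm[2], W = dm[3];
  int Do = out_dhw[0], Ho = out_dhw[1], Wo = out_dhw[2];
  AxisMap md = axis_map(D, Do), mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  NumericVector out((R_xlen_t)C * Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int w = 0; w < Wo; ++w) {
    double ww = mw.w1[w];
    for (int h = 0; h < Ho; ++h) {
      double wh = mh.w1[h];
      for (int d = 0; d < Do; ++d) {
        double wd = md.w1[d];
        double* dst = op + (R_xlen_t)C * (d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * w));
        for (int c = 0; c < C; ++c) dst[c] = 0.0;
        for (int bw = 0; bw < 2; ++bw) {
          int sw = bw ? mw.i1[w] : mw.i0[w];
          double fw = bw ? ww : 1 - ww;
          if (fw == 0) continue;
          for (int bh = 0; bh < 2; ++bh) {
            int sh = bh ? mh.i1[h] : mh.i0[h];
            double fh = bh ? wh : 1 - wh;
            if (fh == 0) continue;
            for (int bd = 0; bd < 2; ++bd) {
              int sd = bd ? md.i1[d] : md.i0[d];
              double f = fw * fh * (bd ? wd : 1 - wd);
              if (f == 0) continue;
              const double* src = xp + (R_xlen_t)C * (sd + (R_xlen_t)D * (sh + (R_xlen_t)H * sw));
              for (int c = 0; c < C; ++c) dst[c] += f * src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_trilinear_fwd (scatter of output gradient onto input grid).
// [[Rcpp::export]]
NumericVector cpp_trilinear_bwd(NumericVector gout, IntegerVector in_dhw) {
  IntegerVector dm = gout.attr("dim");
  int C = dm[0], Do = dm[1], Ho = dm[2], Wo = dm[3];
  int D = in_dhw[0], H = in_dhw[1], W = in_dhw[2];
  AxisMap md = axis_map(D, Do), mh = axis_map(H, Ho), mw = axis_map(W, Wo);
  NumericVector gx((R_xlen_t)C * D * H * W);
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  const double* gp = gout.begin();
  double* xp = gx.begin();
  for (int w = 0; w < Wo; ++w) {
    double ww = mw.w1[w];
    for (int h = 0; h < Ho; ++h) {
      double wh = mh.w1[h];
      for (int d = 0; d < Do; ++d) {
        double wd = md.w1[d];
        const double* src = gp + (R_xlen_t)C * (d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * w));
        for (int bw = 0; bw < 2; ++bw) {
          int sw = bw ? mw.i1[w] : mw.i0[w];
          double fw = bw ? ww : 1 - ww;
          if (fw == 0) continue;
          for (int bh = 0; bh < 2; ++bh) {
            int sh = bh ? mh.i1[h] : mh.i0[h];
            double fh = bh ? wh : 1 - wh;
            if (fh == 0) continue;
            for (int bd = 0; bd < 2; ++bd) {
              int sd = bd ? md.i1[d] : md.i0[d];
              double f = fw * fh * (bd ? wd : 1 - wd);
              if (f == 0) continue;
              double* dst = xp + (R_xlen_t)C * (sd + (R_xlen_t)D * (sh + (R_xlen_t)H * sw));
              for (int c = 0; c < C; ++c) dst[c] += f * src[c];
            }
          }
        }
      }
    }
  }
  return gx;
}
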