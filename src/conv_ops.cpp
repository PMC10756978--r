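// Convolution and max-pooling kernels for the CNN, via im2col + GEMM.
// Layouts: activations are H x W x C x N column-major arrays (R dim order);
// conv weights are a (C*kh*kw) x F matrix, patch index varying as
// (dr, dc, channel) fastest-to-slowest to match R's array flattening.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   arma::mat& cols, int kh, int kw) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  // cols: (kh*kw*C) x (oh*ow)
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      double* dst = cols.colptr(oc * oh + orow);
      int k = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int dc = 0; dc < kw; ++dc) {
          const double* col = xc + (size_t)(oc + dc) * H + orow;
          for (int dr = 0; dr < kh; ++dr) dst[k++] = col[dr];
        }
      }
    }
  }
}

static void col2im_add(double* x, int H, int W, int C,
                       const arma::mat& cols, int kh, int kw) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  for (int oc = 0; oc < ow; ++oc) {
    for (int orow = 0; orow < oh; ++orow) {
      const double* src = cols.colptr(oc * oh + orow);
      int k = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = x + (size_t)c * H * W;
        for (int dc = 0; dc < kw; ++dc) {
          double* col = xc + (size_t)(oc + dc) * H + orow;
          for (int dr = 0; dr < kh; ++dr) col[dr] += src[k++];
        }
      }
    }
  }
}

// x: H x W x C x N, w: (kh*kw*C) x F, b: length F.
// Returns valid convolution, (H-kh+1) x (W-kw+1) x F x N.
// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericMatrix w,
                             NumericVector b, int kh, int kw,
                             bool relu = false) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H - kh + 1, ow = W - kw + 1, F = w.ncol();
  NumericVector out((R_xlen_t)oh * ow * F * N);
  out.attr("dim") = IntegerVector::create(oh, ow, F, N);
  arma::mat wm(w.begin(), w.nrow(), F, false);
  arma::mat cols(kh * kw * C, oh * ow);
  arma::rowvec bv(b.begin(), F);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, cols, kh, kw);
    arma::mat o(out.begin() + (size_t)n * oh * ow * F, oh * ow, F, false, true);
    o = cols.t() * wm;
    o.each_row() += bv;
  }
  if (relu) {
    for (R_xlen_t i = 0; i < out.size(); ++i) if (out[i] < 0) out[i] = 0;
  }
  return out;
}

// Backward pass: returns list(dx, dw, db).
// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dout,
                     int kh, int kw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H - kh + 1, ow = W - kw + 1, F = w.ncol();
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat wm(w.begin(), w.nrow(), F, false);
  arma::mat dwm(w.nrow(), F, arma::fill::zeros);
  arma::rowvec dbv(F, arma::fill::zeros);
  arma::mat cols(kh * kw * C, oh * ow);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, cols, kh, kw);
    arma::mat dom(dout.begin() + (size_t)n * oh * ow * F, oh * ow, F, false);
    dwm += cols * dom;
    dbv += arma::sum(dom, 0);
    arma::mat dcols = wm * dom.t();  // (khkwC) x (oh*ow)
    col2im_add(dx.begin() + (size_t)n * H * W * C, H, W, C, dcols, kh, kw);
  }
  NumericMatrix dw(w.nrow(), F);
  std::copy(dwm.begin(), dwm.end(), dw.begin());
  NumericVector db(F);
  std::copy(dbv.begin(), dbv.end(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling with the given stride. Returns list(out, argmax) where
// argmax holds 1-based linear indices into the input array (for backward).
// [[Rcpp::export]]
List maxpool_forward(NumericVector x, int size, int stride) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = (H - size) / stride + 1, ow = (W - size) / stride + 1;
  NumericVector out((R_xlen_t)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  NumericVector argmax((R_xlen_t)oh * ow * C * N);
  argmax.attr("dim") = IntegerVector::create(oh, ow, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const double* xc = x.begin() + base;
      for (int oc = 0; oc < ow; ++oc) {
        for (int orow = 0; orow < oh; ++orow) {
          const int r0 = orow * stride, c0 = oc * stride;
          double best = xc[(size_t)c0 * H + r0];
          size_t besti = (size_t)c0 * H + r0;
          for (int dc = 0; dc < size; ++dc) {
            for (int dr = 0; dr < size; ++dr) {
              const size_t i = (size_t)(c0 + dc) * H + (r0 + dr);
              if (xc[i] > best) { best = xc[i]; besti = i; }
            }
          }
          // output is iterated in its own column-major order only if the
          // loops match (orow fastest): use explicit index instead.
          const size_t oi = ((size_t)n * C + c) * oh * ow + (size_t)oc * oh + orow;
          out[oi] = best;
          argmax[oi] = (double)(base + besti) + 1.0;
          ++q;
        }
      }
    }
  }
  (void)q;
  return List::create(_["out"] = out, _["argmax"] = argmax);
}

// Scatter-add pooled gradients back to input positions. When `gate` is
// given (the ReLU-activated pre-pool array), gradients are zeroed where the
// activation was clipped at zero (ReLU backward fused in).
// [[Rcpp::export]]
NumericVector maxpool_backward(NumericVector dout, NumericVector argmax,
                               IntegerVector in_dim,
                               Nullable<NumericVector> gate = R_NilValue) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  const R_xlen_t m = dout.size();
  if (gate.isNotNull()) {
    NumericVector g(gate);
    for (R_xlen_t k = 0; k < m; ++k) {
      const size_t i = (size_t)argmax[k] - 1;
      if (g[i] > 0) dx[i] += dout[k];
    }
  } else {
    for (R_xlen_t k = 0; k < m; ++k) {
      dx[(size_t)argmax[k] - 1] += dout[k];
    }
  }
  return dx;
}

// Per-channel batch-norm statistics over (H, W, N) for each channel C.
// Returns biased variance (as used for normalization).
// [[Rcpp::export]]
List bn_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mean[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// out = gamma * (x - mu) * istd + beta, plus xhat for the backward pass.
// [[Rcpp::export]]
List bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
              NumericVector mu, NumericVector istd) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = d;
  xhat.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* po = out.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (p[i] - m) * is;
        ph[i] = xh;
        po[i] = g * xh + b;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// Batch-norm backward: dx = gamma*istd*(dout - mean(dout) - xhat*mean(dout*xhat))
// per channel (means over H*W*N); dgamma = sum(dout*xhat); dbeta = sum(dout).
// [[Rcpp::export]]
List bn_backward_cpp(NumericVector dout, NumericVector xhat,
                     NumericVector gamma, NumericVector istd) {
  IntegerVector d = dout.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dx(dout.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double sd = 0, sdx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* pd = dout.begin() + off;
      const double* ph = xhat.begin() + off;
      for (size_t i = 0; i < hw; ++i) { sd += pd[i]; sdx += pd[i] * ph[i]; }
    }
    dgamma[c] = sdx;
    dbeta[c] = sd;
    const double md = sd / m, mdx = sdx / m, gis = gamma[c] * istd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* pd = dout.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        px[i] = gis * (pd[i] - md - ph[i] * mdx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// In-place-style ReLU returning the activated copy (mask recomputed in R
// from the sign of the activation when needed).
// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0;
  return out;
}
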