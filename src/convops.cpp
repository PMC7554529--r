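#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Batched image tensors are column-major R arrays with dims (H, W, B, C):
// element (h, w, b, c) sits at h + H*(w + W*(b + B*c)).
// im2col/col2im implement same-padded stride-1 convolution as one GEMM
// against a (kh*kw*C) x F weight matrix; pooling is ceil-mode (partial
// windows at the border are kept and clamped to the valid region).

// [[Rcpp::export]]
NumericMatrix im2col_same(NumericVector x, int H, int W, int B, int C,
                          int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  const R_xlen_t N = (R_xlen_t)H * W * B;
  NumericMatrix out(N, kh * kw * C);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        double *dst = po + (R_xlen_t)col * N;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int wi = w + j - pw;
            if (wi < 0 || wi >= W) continue;  // zero padding
            const R_xlen_t obase = (R_xlen_t)H * (w + (R_xlen_t)W * b);
            const double *src =
                px + (R_xlen_t)H * (wi + (R_xlen_t)W * (b + (R_xlen_t)B * c));
            const int h0 = std::max(0, ph - i), h1 = std::min(H, H + ph - i);
            for (int h = h0; h < h1; ++h) dst[obase + h] = src[h + i - ph];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_same(NumericMatrix dcols, int H, int W, int B, int C,
                          int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  const R_xlen_t N = (R_xlen_t)H * W * B;
  NumericVector dx((R_xlen_t)H * W * B * C);
  double *pdx = dx.begin();
  const double *pd = dcols.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * (j + kw * c);
        const double *src = pd + (R_xlen_t)col * N;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int wi = w + j - pw;
            if (wi < 0 || wi >= W) continue;
            const R_xlen_t ibase = (R_xlen_t)H * (w + (R_xlen_t)W * b);
            double *dst =
                pdx + (R_xlen_t)H * (wi + (R_xlen_t)W * (b + (R_xlen_t)B * c));
            const int h0 = std::max(0, ph - i), h1 = std::min(H, H + ph - i);
            for (int h = h0; h < h1; ++h) dst[h + i - ph] += src[ibase + h];
          }
        }
      }
    }
  }
  return dx;
}

static inline int pool_out(int n, int k, int s) {
  return (int)std::ceil((double)(n - k) / s) + 1;
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int H, int W, int B, int C, int k, int s) {
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  const R_xlen_t n_out = (R_xlen_t)Ho * Wo * B * C;
  NumericVector out(n_out);
  IntegerVector arg(n_out);  // 1-based index into x, for the backward pass
  const double *px = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t plane = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * s, w1 = std::min(w0 + k, W);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * s, h1 = std::min(h0 + k, H);
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int w = w0; w < w1; ++w) {
            const R_xlen_t base = plane + (R_xlen_t)H * w;
            for (int h = h0; h < h1; ++h) {
              const double v = px[base + h];
              if (v > best) { best = v; besti = base + h; }
            }
          }
          // out is laid out (Ho, Wo, B, C) but we fill (ho fastest inside wo)
          const R_xlen_t oi = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (b + (R_xlen_t)B * c));
          out[oi] = best;
          arg[oi] = (int)(besti + 1);
          ++o;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector argmax,
                          R_xlen_t n_in) {
  NumericVector dx(n_in);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += dout[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_fwd(NumericVector x, int H, int W, int B, int C, int k,
                          int s) {
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  NumericVector out((R_xlen_t)Ho * Wo * B * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t plane = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * s, w1 = std::min(w0 + k, W);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * s, h1 = std::min(h0 + k, H);
          double acc = 0.0;
          for (int w = w0; w < w1; ++w) {
            const R_xlen_t base = plane + (R_xlen_t)H * w;
            for (int h = h0; h < h1; ++h) acc += px[base + h];
          }
          const R_xlen_t oi = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (b + (R_xlen_t)B * c));
          out[oi] = acc / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, B, C);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd(NumericVector dout, int H, int W, int B, int C,
                          int k, int s) {
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  NumericVector dx((R_xlen_t)H * W * B * C);
  double *pdx = dx.begin();
  const double *pd = dout.begin();
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t plane = (R_xlen_t)H * W * (b + (R_xlen_t)B * c);
      for (int wo = 0; wo < Wo; ++wo) {
        const int w0 = wo * s, w1 = std::min(w0 + k, W);
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = ho * s, h1 = std::min(h0 + k, H);
          const R_xlen_t oi = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * (b + (R_xlen_t)B * c));
          const double g = pd[oi] / ((h1 - h0) * (w1 - w0));
          for (int w = w0; w < w1; ++w) {
            const R_xlen_t base = plane + (R_xlen_t)H * w;
            for (int h = h0; h < h1; ++h) pdx[base + h] += g;
          }
        }
      }
    }
  }
  return dx;
}

// In-place bias add over an (N x F) GEMM output.
// [[Rcpp::export]]
void add_bias_inplace(NumericMatrix out, NumericVector b) {
  const R_xlen_t N = out.nrow();
  for (int f = 0; f < out.ncol(); ++f) {
    double *col = out.begin() + (R_xlen_t)f * N;
    const double bf = b[f];
    for (R_xlen_t i = 0; i < N; ++i) col[i] += bf;
  }
}

// Batch normalization over an (N x C) matrix view of an (H, W, B, C)
// activation (N = H*W*B). Training mode computes batch moments (biased
// variance); inference uses the supplied running moments. Returns the
// normalized output plus xhat and 1/sd for the backward pass.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, int C, NumericVector gamma, NumericVector beta,
            NumericVector mean_in, NumericVector var_in, double eps,
            bool training) {
  const R_xlen_t N = x.size() / C;
  NumericVector out(x.size()), xhat(x.size()), mu(C), v(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double *px = x.begin() + (R_xlen_t)c * N;
    double m, vv;
    if (training) {
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < N; ++i) s += px[i];
      m = s / N;
      for (R_xlen_t i = 0; i < N; ++i) { const double d = px[i] - m; s2 += d * d; }
      vv = s2 / N;
    } else {
      m = mean_in[c];
      vv = var_in[c];
    }
    mu[c] = m; v[c] = vv;
    const double is = 1.0 / std::sqrt(vv + eps);
    istd[c] = is;
    const double g = gamma[c], bb = beta[c];
    double *ph = xhat.begin() + (R_xlen_t)c * N;
    double *po = out.begin() + (R_xlen_t)c * N;
    for (R_xlen_t i = 0; i < N; ++i) {
      const double h = (px[i] - m) * is;
      ph[i] = h;
      po[i] = g * h + bb;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = v, _["istd"] = istd);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector istd,
            NumericVector gamma, int C) {
  const R_xlen_t N = dy.size() / C;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *pd = dy.begin() + (R_xlen_t)c * N;
    const double *ph = xhat.begin() + (R_xlen_t)c * N;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < N; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], is = istd[c];
    const double mg = sb / N, mgh = sg / N;
    double *px = dx.begin() + (R_xlen_t)c * N;
    for (R_xlen_t i = 0; i < N; ++i)
      px[i] = is * g * (pd[i] - mg - ph[i] * mgh);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ReLU forward returning the value and retaining sign info via the value
// itself (backward multiplies by (out > 0)).
// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}
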