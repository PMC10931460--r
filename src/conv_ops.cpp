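// Convolution / pooling kernels for the tape autodiff engine.
// Array layout follows R column-major order: images (H, W, C, N),
// kernels (kh, kw, Cin, Cout).  im2col rows are indexed ki + kh*(kj + kw*c)
// so a flattened R kernel array maps directly onto the weight matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[hi + (size_t)H * (wi + (size_t)W * c)];
            col(row, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(double* dx, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, const arma::mat& dcol) {
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            dx[hi + (size_t)H * (wi + (size_t)W * c)] +=
              dcol(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout,
               false, true);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  arma::mat col((size_t)kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat O(out.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo,
                Cout, false, true);
    O = col.t() * Wm;
    for (int c = 0; c < Cout; ++c) O.col(c) += b[c];
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector od = dout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = od[0], Wo = od[1];
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout,
               false, true);
  NumericVector dx((size_t)H * W * C * N);
  NumericVector dw((size_t)kh * kw * C * Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::mat col((size_t)kh * kw * C, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat dO(const_cast<double*>(dout.begin()) + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    dWm += col * dO;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dO.col(c));
    arma::mat dcol = Wm * dO.t();
    col2im_add(dx.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride,
               pad, Ho, Wo, dcol);
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor mode.  Returns pooled values plus the
// 1-based linear argmax index into each input (H*W*C*N) block for backward.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    size_t obase = (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              size_t idx = (size_t)(2 * ho + di) +
                           (size_t)H * ((2 * wo + dj) + (size_t)W * c);
              if (xs[idx] > best) { best = xs[idx]; besti = idx; }
            }
          }
          size_t oidx = obase + ho + (size_t)Ho * (wo + (size_t)Wo * c);
          out[oidx] = best;
          arg[oidx] = (int)besti + 1;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector argmax,
                               IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector od = dout.attr("dim");
  size_t per_out = (size_t)od[0] * od[1] * od[2];
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    double* dxs = dx.begin() + (size_t)n * H * W * C;
    size_t obase = (size_t)n * per_out;
    for (size_t i = 0; i < per_out; ++i)
      dxs[argmax[obase + i] - 1] += dout[obase + i];
  }
  dx.attr("dim") = xdim;
  return dx;
}
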