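// Low-level CPU kernels for the conv-net layers and nonlocal-means filtering.
// Tensors follow R array layout: images are (H, W, C, N) column-major,
// conv weights are (kh, kw, Cin, Cout). im2col uses a (HoWo x kh*kw*Cin)
// patch matrix so the GEMM output lands directly in R's (Ho, Wo, Cout) order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the patch matrix rows for one sample inside a (groupRows x P)
// column-major buffer: column p starts at Kbase + p*ld + rowOff.
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* Kbase, size_t ld, size_t rowOff) {
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int p = ki + kh * (kj + kw * c);
        double* Kp = Kbase + (size_t)p * ld + rowOff;
        // valid output-row range for this kernel offset
        int io_lo = std::max(0, (pad - ki + stride - 1) / stride);
        int io_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int jo = 0; jo < Wo; ++jo) {
          int j = jo * stride + kj - pad;
          double* Kcol = Kp + (size_t)Ho * jo;
          if (j < 0 || j >= W) {
            std::fill(Kcol, Kcol + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * j;
          if (io_lo > 0) std::fill(Kcol, Kcol + io_lo, 0.0);
          if (io_hi < Ho - 1) std::fill(Kcol + io_hi + 1, Kcol + Ho, 0.0);
          if (stride == 1) {
            std::memcpy(Kcol + io_lo, xcol + io_lo + ki - pad,
                        (size_t)(io_hi - io_lo + 1) * sizeof(double));
          } else {
            for (int io = io_lo; io <= io_hi; ++io)
              Kcol[io] = xcol[io * stride + ki - pad];
          }
        }
      }
    }
  }
}

// Scatter-add of the patch-gradient matrix back onto the input gradient.
static void col2im(const double* dKbase, size_t ld, size_t rowOff,
                   int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int p = ki + kh * (kj + kw * c);
        const double* Kp = dKbase + (size_t)p * ld + rowOff;
        int io_lo = std::max(0, (pad - ki + stride - 1) / stride);
        int io_hi = std::min(Ho - 1, (H - 1 + pad - ki) / stride);
        for (int jo = 0; jo < Wo; ++jo) {
          int j = jo * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          const double* Kcol = Kp + (size_t)Ho * jo;
          double* dxcol = dxc + (size_t)H * j;
          if (stride == 1) {
            double* d = dxcol + io_lo + ki - pad;
            for (int io = io_lo; io <= io_hi; ++io) d[io - io_lo] += Kcol[io];
          } else {
            for (int io = io_lo; io <= io_hi; ++io)
              dxcol[io * stride + ki - pad] += Kcol[io];
          }
        }
      }
    }
  }
}

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cppConvForward")]]
NumericVector cpp_conv_forward(NumericVector x, IntegerVector xdim,
                               NumericVector w, IntegerVector wdim,
                               NumericVector bias, int stride, int pad) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int P = kh * kw * Cin;
  size_t hw = (size_t)Ho * Wo;
  NumericVector y(hw * Cout * N);
  arma::mat Wm(const_cast<double*>(w.begin()), P, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(bias.begin()), Cout, false, true);
  arma::mat K(hw, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
           kh, kw, stride, pad, Ho, Wo, K.memptr(), hw, 0);
    arma::mat Yn(y.begin() + hw * Cout * n, hw, Cout, false, true);
    Yn = K * Wm;
    Yn.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".cppConvBackward")]]
List cpp_conv_backward(NumericVector x, IntegerVector xdim,
                       NumericVector w, IntegerVector wdim,
                       NumericVector dy, int stride, int pad) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int P = kh * kw * Cin;
  size_t hw = (size_t)Ho * Wo;
  NumericVector dx((size_t)H * W * Cin * N);
  NumericVector dw((size_t)P * Cout);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), P, Cout, false, true);
  arma::mat dWm(dw.begin(), P, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat K(hw, P);
  arma::mat dK(hw, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
           kh, kw, stride, pad, Ho, Wo, K.memptr(), hw, 0);
    arma::mat dYn(const_cast<double*>(dy.begin()) + hw * Cout * n,
                  hw, Cout, false, true);
    dWm += K.t() * dYn;
    dbv += arma::sum(dYn, 0).t();
    dK = dYn * Wm.t();
    col2im(dK.memptr(), hw, 0, H, W, Cin, kh, kw, stride, pad,
           Ho, Wo, dx.begin() + (size_t)H * W * Cin * n);
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transposed convolution with a 2x2 kernel and stride 2 (learned 2x upsampling):
// y[2i+a, 2j+b, co] = sum_ci x[i, j, ci] * w[a, b, ci, co] + bias[co].
// [[Rcpp::export(name = ".cppUpconvForward")]]
NumericVector cpp_upconv_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int Cout = wdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  // view weights as (4*Cin) x Cout after permuting: w(a,b,ci,co)
  arma::mat Wm(const_cast<double*>(w.begin()), 4 * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                (size_t)H * W, Cin, false, true);
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (size_t)Ho * Wo * co;
      std::fill(yc, yc + (size_t)Ho * Wo, bias[co]);
      for (int b = 0; b < 2; ++b) {
        for (int a = 0; a < 2; ++a) {
          // accumulate sum_ci X(:,ci) * w(a,b,ci,co) into strided positions
          arma::vec acc = arma::zeros(H * (size_t)W);
          for (int ci = 0; ci < Cin; ++ci)
            acc += Wm(a + 2 * b + 4 * ci, co) * X.col(ci);
          const double* av = acc.memptr();
          for (int j = 0; j < W; ++j) {
            double* ycol = yc + (size_t)Ho * (2 * j + b);
            const double* acol = av + (size_t)H * j;
            for (int i = 0; i < H; ++i) ycol[2 * i + a] += acol[i];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".cppUpconvBackward")]]
List cpp_upconv_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector dy) {
  int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  int Cout = wdim[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * Cin * N);
  NumericVector dw((size_t)4 * Cin * Cout);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), 4 * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), 4 * Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * Cin * n,
                (size_t)H * W, Cin, false, true);
    arma::mat dX(dx.begin() + (size_t)H * W * Cin * n, (size_t)H * W, Cin,
                 false, true);
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (size_t)Ho * Wo * co;
      double s = 0.0;
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t) s += dyc[t];
      db[co] += s;
      for (int b = 0; b < 2; ++b) {
        for (int a = 0; a < 2; ++a) {
          // gather strided slice of dy into g (H*W)
          arma::vec g(H * (size_t)W);
          double* gv = g.memptr();
          for (int j = 0; j < W; ++j) {
            const double* ycol = dyc + (size_t)Ho * (2 * j + b);
            double* gcol = gv + (size_t)H * j;
            for (int i = 0; i < H; ++i) gcol[i] = ycol[2 * i + a];
          }
          for (int ci = 0; ci < Cin; ++ci) {
            dWm(a + 2 * b + 4 * ci, co) += arma::dot(g, X.col(ci));
            dX.col(ci) += Wm(a + 2 * b + 4 * ci, co) * g;
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and argmax linear indices
// (0-based within each (H, W) plane) for the backward pass.
// [[Rcpp::export(name = ".cppMaxpoolForward")]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  size_t t = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          int i0 = 2 * io, j0 = 2 * jo;
          int best = i0 + H * j0;
          double bv = xc[best];
          int cand[3] = {i0 + 1 + H * j0, i0 + H * (j0 + 1),
                         i0 + 1 + H * (j0 + 1)};
          for (int q = 0; q < 3; ++q)
            if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          y[t] = bv;
          idx[t] = best;
          ++t;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cppMaxpoolBackward")]]
NumericVector cpp_maxpool_backward(IntegerVector idx, NumericVector dy,
                                   IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  size_t plane = (size_t)H * W;
  size_t npool = dy.size();
  NumericVector dx(plane * C * N);
  int Ho = H / 2, Wo = W / 2;
  size_t per = (size_t)Ho * Wo;
  for (size_t t = 0; t < npool; ++t) {
    size_t cn = t / per;
    dx[plane * cn + idx[t]] += dy[t];
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Generic feature-weighted nonlocal means: the value image is averaged with
// weights exp(-||f_i - f_j||^2 / h^2) computed from patches of the feature
// stack (H, W, Cf). With the value image itself as the single feature this is
// plain NLM denoising; with anatomical priors as features it is FNLM
// reinterpolation. Patch distances are mean squared differences over the
// patch and feature channels; out-of-image patch pixels are clamped to the
// border.
// [[Rcpp::export(name = ".cppNlmFilter")]]
NumericMatrix cpp_nlm_filter(NumericMatrix value, NumericVector feat,
                             IntegerVector fdim, int patchR, int searchR,
                             double h) {
  int H = fdim[0], W = fdim[1], Cf = fdim[2];
  NumericMatrix out(H, W);
  const double h2 = h * h;
  const int psz = (2 * patchR + 1) * (2 * patchR + 1) * Cf;
  auto clampi = [](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double wsum = 0.0, vsum = 0.0;
      for (int dj = -searchR; dj <= searchR; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -searchR; di <= searchR; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          double d2 = 0.0;
          for (int c = 0; c < Cf; ++c) {
            const double* fc = feat.begin() + (size_t)H * W * c;
            for (int pj = -patchR; pj <= patchR; ++pj) {
              int aj = clampi(j + pj, 0, W - 1);
              int bj = clampi(jj + pj, 0, W - 1);
              for (int pi = -patchR; pi <= patchR; ++pi) {
                int ai = clampi(i + pi, 0, H - 1);
                int bi = clampi(ii + pi, 0, H - 1);
                double df = fc[ai + (size_t)H * aj] - fc[bi + (size_t)H * bj];
                d2 += df * df;
              }
            }
          }
          d2 /= psz;
          double wgt = std::exp(-d2 / h2);
          wsum += wgt;
          vsum += wgt * value(ii, jj);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
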