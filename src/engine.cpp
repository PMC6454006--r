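// Numerical core of the network engine: convolution (direct / grouped /
// transpose) and resampling primitives with their gradients. Feature maps are
// R arrays in column-major layout dim = (H, W, C, N); conv weights are
// (kh, kw, cin_per_group, cout); transpose-conv weights are (2, 2, cin, cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// im2col for one sample/group slab. x points at the (H,W) plane of channel 0
// of the slab; channel stride is H*W.
static void im2col(const double* x, int H, int W, int cig,
                   int kh, int kw, int stride, int ph0, int pw0,
                   int oh, int ow, arma::mat& col) {
  // col is (kh*kw*cig) x (oh*ow); row r = dh + kh*(dw + kw*ci)
  col.zeros();
  for (int ci = 0; ci < cig; ++ci) {
    const double* xp = x + (size_t)ci * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        for (int oj = 0; oj < ow; ++oj) {
          const int iw = oj * stride - pw0 + dw;
          if (iw < 0 || iw >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int ih = oi * stride - ph0 + dh;
            if (ih < 0 || ih >= H) continue;
            col(r, oi + oh * oj) = xp[ih + H * iw];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, double* dx, int H, int W, int cig,
                       int kh, int kw, int stride, int ph0, int pw0,
                       int oh, int ow) {
  for (int ci = 0; ci < cig; ++ci) {
    double* xp = dx + (size_t)ci * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        for (int oj = 0; oj < ow; ++oj) {
          const int iw = oj * stride - pw0 + dw;
          if (iw < 0 || iw >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int ih = oi * stride - ph0 + dh;
            if (ih < 0 || ih >= H) continue;
            xp[ih + H * iw] += col(r, oi + oh * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int ph0, int pw0, int oh, int ow,
                       int groups) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cig = wd[2], cout = wd[3];
  if (C != cig * groups) stop("input channels do not match weight shape");
  const int cog = cout / groups;
  NumericVector y = make4d(oh, ow, cout, N);
  arma::mat col(kh * kw * cig, oh * ow);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xg = x.begin() + (size_t)H * W * (g * cig + (size_t)C * n);
      im2col(xg, H, W, cig, kh, kw, stride, ph0, pw0, oh, ow, col);
      const arma::mat Wg(const_cast<double*>(w.begin()) +
                             (size_t)kh * kw * cig * (g * cog),
                         kh * kw * cig, cog, false, true);
      arma::mat Yg = col.t() * Wg;  // (oh*ow) x cog
      for (int o = 0; o < cog; ++o) {
        double* yp = y.begin() + (size_t)oh * ow * (g * cog + o + (size_t)cout * n);
        const double bo = b[g * cog + o];
        const double* src = Yg.colptr(o);
        for (int p = 0; p < oh * ow; ++p) yp[p] = src[p] + bo;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
              int stride, int ph0, int pw0, int groups) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cig = wd[2], cout = wd[3];
  const int cog = cout / groups;
  IntegerVector yd = dy.attr("dim");
  const int oh = yd[0], ow = yd[1];
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dw = make4d(kh, kw, cig, cout);
  NumericVector db(cout);
  arma::mat col(kh * kw * cig, oh * ow);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xg = x.begin() + (size_t)H * W * (g * cig + (size_t)C * n);
      im2col(xg, H, W, cig, kh, kw, stride, ph0, pw0, oh, ow, col);
      arma::mat dYg(oh * ow, cog);
      for (int o = 0; o < cog; ++o) {
        const double* dyp = dy.begin() +
            (size_t)oh * ow * (g * cog + o + (size_t)cout * n);
        std::copy(dyp, dyp + (size_t)oh * ow, dYg.colptr(o));
        double s = 0; for (int p = 0; p < oh * ow; ++p) s += dyp[p];
        db[g * cog + o] += s;
      }
      arma::mat dWg_view(dw.begin() + (size_t)kh * kw * cig * (g * cog),
                         kh * kw * cig, cog, false, true);
      dWg_view += col * dYg;
      const arma::mat Wg(const_cast<double*>(w.begin()) +
                             (size_t)kh * kw * cig * (g * cog),
                         kh * kw * cig, cog, false, true);
      arma::mat dcol = Wg * dYg.t();
      col2im_add(dcol, dx.begin() + (size_t)H * W * (g * cig + (size_t)C * n),
                 H, W, cig, kh, kw, stride, ph0, pw0, oh, ow);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Transpose convolution, fixed 2x2 kernel, stride 2: exact size doubling.
// [[Rcpp::export(name = ".tconv_fwd")]]
NumericVector tconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  if (cin != C) stop("input channels do not match weight shape");
  const int oh = 2 * H, ow = 2 * W;
  NumericVector y = make4d(oh, ow, cout, N);
  for (int n = 0; n < N; ++n) {
    const arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                       H * W, C, false, true);
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        arma::mat Wab(cin, cout);
        for (int o = 0; o < cout; ++o)
          for (int ci = 0; ci < cin; ++ci)
            Wab(ci, o) = w[a + 2 * bb + 4 * ci + (size_t)4 * cin * o];
        arma::mat Yab = Xn * Wab;  // (H*W) x cout
        for (int o = 0; o < cout; ++o) {
          double* yp = y.begin() + (size_t)oh * ow * (o + (size_t)cout * n);
          const double* src = Yab.colptr(o);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yp[(2 * i + a) + oh * (2 * j + bb)] = src[i + H * j];
        }
      }
    }
    for (int o = 0; o < cout; ++o) {
      double* yp = y.begin() + (size_t)oh * ow * (o + (size_t)cout * n);
      for (int p = 0; p < oh * ow; ++p) yp[p] += b[o];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv_bwd")]]
List tconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int oh = 2 * H, ow = 2 * W;
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dw = make4d(2, 2, cin, cout);
  NumericVector db(cout);
  for (int n = 0; n < N; ++n) {
    const arma::mat Xn(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                       H * W, C, false, true);
    arma::mat dXn(dx.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    for (int a = 0; a < 2; ++a) {
      for (int bb = 0; bb < 2; ++bb) {
        arma::mat dYab(H * W, cout);
        for (int o = 0; o < cout; ++o) {
          const double* dyp = dy.begin() + (size_t)oh * ow * (o + (size_t)cout * n);
          double* dst = dYab.colptr(o);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[i + H * j] = dyp[(2 * i + a) + oh * (2 * j + bb)];
        }
        arma::mat Wab(cin, cout);
        for (int o = 0; o < cout; ++o)
          for (int ci = 0; ci < cin; ++ci)
            Wab(ci, o) = w[a + 2 * bb + 4 * ci + (size_t)4 * cin * o];
        arma::mat dWab = Xn.t() * dYab;  // cin x cout
        for (int o = 0; o < cout; ++o)
          for (int ci = 0; ci < cin; ++ci)
            dw[a + 2 * bb + 4 * ci + (size_t)4 * cin * o] += dWab(ci, o);
        dXn += dYab * Wab.t();
      }
    }
    for (int o = 0; o < cout; ++o) {
      const double* dyp = dy.begin() + (size_t)oh * ow * (o + (size_t)cout * n);
      double s = 0; for (int p = 0; p < oh * ow; ++p) s += dyp[p];
      db[o] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".resize_nn_fwd")]]
NumericVector resize_nn_fwd(NumericVector x, int oh, int ow) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector y = make4d(oh, ow, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        const int iw = std::min(W - 1, (int)((long long)j * W / ow));
        for (int i = 0; i < oh; ++i) {
          const int ih = std::min(H - 1, (int)((long long)i * H / oh));
          yp[i + oh * j] = xp[ih + H * iw];
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".resize_nn_bwd")]]
NumericVector resize_nn_bwd(NumericVector dy, int H, int W) {
  int oh, ow, C, N; dims4(dy, oh, ow, C, N);
  NumericVector dx = make4d(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yp = dy.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        const int iw = std::min(W - 1, (int)((long long)j * W / ow));
        for (int i = 0; i < oh; ++i) {
          const int ih = std::min(H - 1, (int)((long long)i * H / oh));
          xp[ih + H * iw] += yp[i + oh * j];
        }
      }
    }
  return dx;
}

// [[Rcpp::export(name = ".resize_bl_fwd")]]
NumericVector resize_bl_fwd(NumericVector x, int oh, int ow) {
  int H, W, C, N; dims4(x, H, W, C, N);
  NumericVector y = make4d(oh, ow, C, N);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yp = y.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        double sc = (j + 0.5) * sw - 0.5;
        sc = std::min(std::max(sc, 0.0), (double)(W - 1));
        const int c0 = (int)sc, c1 = std::min(c0 + 1, W - 1);
        const double fc = sc - c0;
        for (int i = 0; i < oh; ++i) {
          double sr = (i + 0.5) * sh - 0.5;
          sr = std::min(std::max(sr, 0.0), (double)(H - 1));
          const int r0 = (int)sr, r1 = std::min(r0 + 1, H - 1);
          const double fr = sr - r0;
          yp[i + oh * j] =
              (1 - fr) * (1 - fc) * xp[r0 + H * c0] +
              (1 - fr) * fc * xp[r0 + H * c1] +
              fr * (1 - fc) * xp[r1 + H * c0] +
              fr * fc * xp[r1 + H * c1];
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".resize_bl_bwd")]]
NumericVector resize_bl_bwd(NumericVector dy, int H, int W) {
  int oh, ow, C, N; dims4(dy, oh, ow, C, N);
  NumericVector dx = make4d(H, W, C, N);
  const double sh = (double)H / oh, sw = (double)W / ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yp = dy.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        double sc = (j + 0.5) * sw - 0.5;
        sc = std::min(std::max(sc, 0.0), (double)(W - 1));
        const int c0 = (int)sc, c1 = std::min(c0 + 1, W - 1);
        const double fc = sc - c0;
        for (int i = 0; i < oh; ++i) {
          double sr = (i + 0.5) * sh - 0.5;
          sr = std::min(std::max(sr, 0.0), (double)(H - 1));
          const int r0 = (int)sr, r1 = std::min(r0 + 1, H - 1);
          const double fr = sr - r0;
          const double g = yp[i + oh * j];
          xp[r0 + H * c0] += (1 - fr) * (1 - fc) * g;
          xp[r0 + H * c1] += (1 - fr) * fc * g;
          xp[r1 + H * c0] += fr * (1 - fc) * g;
          xp[r1 + H * c1] += fr * fc * g;
        }
      }
    }
  return dx;
}
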