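// Low-level numerical kernels: im2col convolution (forward/backward),
// differentiable bilinear warping, nearest-neighbour warping, and sliding
// box sums (used by the patchwise SSIM machinery).
//
// Array conventions (match the R side):
//   images        : H x W matrices, rows = y, columns = x
//   feature maps  : H x W x C x N arrays (column-major, R layout)
//   conv weights  : kh x kw x Cin x Cout arrays
//   displacement  : separate dx, dy matrices in normalized coordinates,
//                   grid spanning [-1, 1] with align-corners pixel centers
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Build the column matrix for one sample: rows indexed (a + kh*b + kh*kw*c)
// over kernel row a, kernel col b, input channel c; columns indexed
// (i + Ho*j) over output pixels. Zero padding outside the input.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int s, int p,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        int r = a + kh * (b + kw * c);
        double* dst = col.memptr() + (size_t)r; // stride col.n_rows per column
        for (int j = 0; j < Wo; ++j) {
          int wj = j * s - p + b;
          bool wok = (wj >= 0 && wj < W);
          for (int i = 0; i < Ho; ++i) {
            int hi = i * s - p + a;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wj];
            dst[(size_t)(i + Ho * j) * col.n_rows] = v;
          }
        }
      }
    }
  }
}

// Scatter-add the column-matrix gradient back to input layout (adjoint of
// im2col).
static void col2im(const arma::mat& gcol, int H, int W, int C,
                   int kh, int kw, int s, int p,
                   int Ho, int Wo, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        int r = a + kh * (b + kw * c);
        const double* src = gcol.memptr() + (size_t)r;
        for (int j = 0; j < Wo; ++j) {
          int wj = j * s - p + b;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int hi = i * s - p + a;
            if (hi < 0 || hi >= H) continue;
            gc[hi + (size_t)H * wj] += src[(size_t)(i + Ho * j) * gcol.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int K = kh * kw * Cin, Q = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, Q);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat om(out.begin() + (size_t)Q * Cout * n, Q, Cout, false, true);
    om = col.t() * Wm; // Q x Cout, column-major => [Ho,Wo,Cout] layout
    for (int co = 0; co < Cout; ++co) om.col(co) += bias[co];
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                int stride, int pad, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  int K = kh * kw * Cin, Q = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gw((size_t)K * Cout);
  gw.attr("dim") = wd;
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  NumericVector gb(Cout);
  NumericVector gx(need_gx ? (size_t)H * W * C * N : 0);
  if (need_gx) gx.attr("dim") = xd;
  arma::mat col(K, Q);
  for (int n = 0; n < N; ++n) {
    arma::mat gm(const_cast<double*>(gout.begin()) + (size_t)Q * Cout * n,
                 Q, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    Gw += col * gm;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gm.col(co));
    if (need_gx) {
      arma::mat gcol = Wm * gm.t(); // K x Q
      col2im(gcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
             gx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["gw"] = gw, _["gb"] = gb,
                      _["gx"] = need_gx ? SEXP(gx) : R_NilValue);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Backward-warp a single-channel image: out(i,j) = I(p + d(p)) sampled
// bilinearly in pixel space, border-replicated. dx/dy are displacements in
// normalized ([-1,1], align-corners) coordinates and define the output
// grid, which may have a different resolution than the image.
// [[Rcpp::export(name = ".warp_bilinear")]]
NumericMatrix warp_bilinear(NumericMatrix img, NumericMatrix dx,
                            NumericMatrix dy) {
  int H = img.nrow(), W = img.ncol();
  int Ho = dx.nrow(), Wo = dx.ncol();
  NumericMatrix out(Ho, Wo);
  double sx = (W - 1) / 2.0, sy = (H - 1) / 2.0;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      // output-grid pixel mapped into the sampled image's pixel
      // coordinates, plus the displacement rescaled from normalized
      // units; when the grids match, a zero displacement is exact
      double rx = Wo > 1 ? (W - 1.0) / (Wo - 1.0) : 0.0;
      double ry = Ho > 1 ? (H - 1.0) / (Ho - 1.0) : 0.0;
      double px = j * rx + dx(i, j) * sx;
      double py = i * ry + dy(i, j) * sy;
      px = clampd(px, 0.0, W - 1.0);
      py = clampd(py, 0.0, H - 1.0);
      int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
      if (x0 > W - 2) x0 = W - 2;
      if (y0 > H - 2) y0 = H - 2;
      double fx = px - x0, fy = py - y0;
      out(i, j) =
        img(y0, x0) * (1 - fx) * (1 - fy) + img(y0, x0 + 1) * fx * (1 - fy) +
        img(y0 + 1, x0) * (1 - fx) * fy + img(y0 + 1, x0 + 1) * fx * fy;
    }
  }
  return out;
}

// Gradients of the bilinear warp w.r.t. the image and both displacement
// channels. Positions clamped at the border get zero positional gradient
// (the sample saturates there).
// [[Rcpp::export(name = ".warp_bilinear_bwd")]]
List warp_bilinear_bwd(NumericMatrix img, NumericMatrix dx, NumericMatrix dy,
                       NumericMatrix gout, bool need_gimg) {
  int H = img.nrow(), W = img.ncol();
  int Ho = dx.nrow(), Wo = dx.ncol();
  NumericMatrix gdx(Ho, Wo), gdy(Ho, Wo);
  NumericMatrix gimg(need_gimg ? H : 1, need_gimg ? W : 1);
  double sx = (W - 1) / 2.0, sy = (H - 1) / 2.0;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double g = gout(i, j);
      double rx = Wo > 1 ? (W - 1.0) / (Wo - 1.0) : 0.0;
      double ry = Ho > 1 ? (H - 1.0) / (Ho - 1.0) : 0.0;
      double px = j * rx + dx(i, j) * sx;
      double py = i * ry + dy(i, j) * sy;
      bool inx = (px > 0.0 && px < W - 1.0);
      bool iny = (py > 0.0 && py < H - 1.0);
      px = clampd(px, 0.0, W - 1.0);
      py = clampd(py, 0.0, H - 1.0);
      int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
      if (x0 > W - 2) x0 = W - 2;
      if (y0 > H - 2) y0 = H - 2;
      double fx = px - x0, fy = py - y0;
      double i00 = img(y0, x0), i01 = img(y0, x0 + 1);
      double i10 = img(y0 + 1, x0), i11 = img(y0 + 1, x0 + 1);
      double dpx = (1 - fy) * (i01 - i00) + fy * (i11 - i10);
      double dpy = (1 - fx) * (i10 - i00) + fx * (i11 - i01);
      gdx(i, j) = inx ? g * dpx * sx : 0.0;
      gdy(i, j) = iny ? g * dpy * sy : 0.0;
      if (need_gimg) {
        gimg(y0, x0) += g * (1 - fx) * (1 - fy);
        gimg(y0, x0 + 1) += g * fx * (1 - fy);
        gimg(y0 + 1, x0) += g * (1 - fx) * fy;
        gimg(y0 + 1, x0 + 1) += g * fx * fy;
      }
    }
  }
  return List::create(_["gdx"] = gdx, _["gdy"] = gdy,
                      _["gimg"] = need_gimg ? SEXP(gimg) : R_NilValue);
}

// [[Rcpp::export(name = ".warp_nearest")]]
NumericMatrix warp_nearest(NumericMatrix img, NumericMatrix dx,
                           NumericMatrix dy) {
  int H = img.nrow(), W = img.ncol();
  int Ho = dx.nrow(), Wo = dx.ncol();
  NumericMatrix out(Ho, Wo);
  double sx = (W - 1) / 2.0, sy = (H - 1) / 2.0;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double rx = Wo > 1 ? (W - 1.0) / (Wo - 1.0) : 0.0;
      double ry = Ho > 1 ? (H - 1.0) / (Ho - 1.0) : 0.0;
      int x0 = (int)std::lround(clampd(j * rx + dx(i, j) * sx, 0.0, W - 1.0));
      int y0 = (int)std::lround(clampd(i * ry + dy(i, j) * sy, 0.0, H - 1.0));
      out(i, j) = img(y0, x0);
    }
  }
  return out;
}

// Sliding k x k window sums over all fully interior windows.
// [[Rcpp::export(name = ".box_sum_valid")]]
NumericMatrix box_sum_valid(NumericMatrix x, int k) {
  int H = x.nrow(), W = x.ncol();
  int Ho = H - k + 1, Wo = W - k + 1;
  NumericMatrix out(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      double s = 0.0;
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a) s += x(i + a, j + b);
      out(i, j) = s;
    }
  return out;
}

// Adjoint of box_sum_valid: scatter each window gradient onto its k x k
// support.
// [[Rcpp::export(name = ".box_sum_scatter")]]
NumericMatrix box_sum_scatter(NumericMatrix g, int k, int H, int W) {
  NumericMatrix out(H, W);
  int Ho = g.nrow(), Wo = g.ncol();
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i) {
      double v = g(i, j);
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a) out(i + a, j + b) += v;
    }
  return out;
}
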