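// Low-level numeric kernels: 2-D convolution stacks for the U-Net
// (forward + backward), 2x2 max-pooling, 2x2 stride-2 transposed
// convolution, breadth-first seeded region growing, and a separable
// Gaussian blur. Arrays are R column-major: element (i,j,c) of an
// H x W x C array sits at i + H*j + H*W*c (0-based).
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Same-padded cross-correlation: x (H,W,Cin) * w (kh,kw,Cin,Cout) + b (Cout).
// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector y(H * (R_xlen_t)W * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bb = b[co];
    double *ych = yp + (R_xlen_t)H * W * co;
    for (R_xlen_t q = 0; q < (R_xlen_t)H * W; ++q) ych[q] = bb;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xch = xp + (R_xlen_t)H * W * ci;
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          double ww = wp[di + kh * dj + kh * kw * ci + kh * kw * Cin * co];
          int oi = di - ph, oj = dj - pw;
          int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xch + (R_xlen_t)H * (j + oj);
            double *ycol = ych + (R_xlen_t)H * j;
            for (int i = i0; i < i1; ++i) ycol[i] += ww * xcol[i + oi];
          }
        }
      }
    }
  }
  return y;
}

// Gradients of the same-padded convolution w.r.t. input, weights, bias.
// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx(H * (R_xlen_t)W * Cin), gw(kh * (R_xlen_t)kw * Cin * Cout), gb(Cout);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = wd;
  const double *xp = x.begin(), *wp = w.begin(), *gyp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gch = gyp + (R_xlen_t)H * W * co;
    double acc_b = 0;
    for (R_xlen_t q = 0; q < (R_xlen_t)H * W; ++q) acc_b += gch[q];
    gb[co] = acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xch = xp + (R_xlen_t)H * W * ci;
      double *gxch = gxp + (R_xlen_t)H * W * ci;
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          R_xlen_t wi = di + kh * dj + kh * kw * ci + (R_xlen_t)kh * kw * Cin * co;
          double ww = wp[wi], acc_w = 0;
          int oi = di - ph, oj = dj - pw;
          int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          for (int j = j0; j < j1; ++j) {
            const double *xcol = xch + (R_xlen_t)H * (j + oj);
            double *gxcol = gxch + (R_xlen_t)H * (j + oj);
            const double *gcol = gch + (R_xlen_t)H * j;
            for (int i = i0; i < i1; ++i) {
              double g = gcol[i];
              acc_w += g * xcol[i + oi];
              gxcol[i + oi] += ww * g;
            }
          }
          gwp[wi] = acc_w;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; H and W must be even. Returns pooled values and
// the 0-based linear argmax indices into x (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * (R_xlen_t)Wo * C);
  IntegerVector idx(Ho * (R_xlen_t)Wo * C);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        R_xlen_t base = (R_xlen_t)2 * i + (R_xlen_t)H * 2 * j + (R_xlen_t)H * W * c;
        R_xlen_t cand[4] = {base, base + 1, base + H, base + H + 1};
        R_xlen_t best = cand[0];
        for (int q = 1; q < 4; ++q)
          if (xp[cand[q]] > xp[best]) best = cand[q];
        R_xlen_t o = i + (R_xlen_t)Ho * j + (R_xlen_t)Ho * Wo * c;
        yp[o] = xp[best];
        ip[o] = (int)best;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[2];
  NumericVector gx(H * (R_xlen_t)W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  const double *gp = gy.begin();
  const int *ip = idx.begin();
  double *xp = gx.begin();
  for (R_xlen_t q = 0; q < gy.size(); ++q) xp[ip[q]] += gp[q];
  return gx;
}

// Transposed convolution, kernel 2x2, stride 2 (exact cover, no overlap):
// y[2i+di, 2j+dj, co] = b[co] + sum_ci x[i,j,ci] * w[di,dj,ci,co].
// [[Rcpp::export]]
NumericVector cpp_upconv_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * (R_xlen_t)Wo * Cout);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bb = b[co];
    double *ych = yp + (R_xlen_t)Ho * Wo * co;
    for (R_xlen_t q = 0; q < (R_xlen_t)Ho * Wo; ++q) ych[q] = bb;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xch = xp + (R_xlen_t)H * W * ci;
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double ww = wp[di + 2 * dj + 4 * ci + 4 * Cin * co];
          for (int j = 0; j < W; ++j) {
            const double *xcol = xch + (R_xlen_t)H * j;
            double *ycol = ych + (R_xlen_t)Ho * (2 * j + dj) + di;
            for (int i = 0; i < H; ++i) ycol[2 * i] += ww * xcol[i];
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx(H * (R_xlen_t)W * Cin), gw(4 * (R_xlen_t)Cin * Cout), gb(Cout);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  gw.attr("dim") = wd;
  const double *xp = x.begin(), *wp = w.begin(), *gp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double *gch = gp + (R_xlen_t)Ho * Wo * co;
    double acc_b = 0;
    for (R_xlen_t q = 0; q < (R_xlen_t)Ho * Wo; ++q) acc_b += gch[q];
    gb[co] = acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xch = xp + (R_xlen_t)H * W * ci;
      double *gxch = gxp + (R_xlen_t)H * W * ci;
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          R_xlen_t wi = di + 2 * dj + 4 * ci + (R_xlen_t)4 * Cin * co;
          double ww = wp[wi], acc_w = 0;
          for (int j = 0; j < W; ++j) {
            const double *xcol = xch + (R_xlen_t)H * j;
            double *gxcol = gxch + (R_xlen_t)H * j;
            const double *gcol = gch + (R_xlen_t)Ho * (2 * j + dj) + di;
            for (int i = 0; i < H; ++i) {
              double g = gcol[2 * i];
              acc_w += g * xcol[i];
              gxcol[i] += ww * g;
            }
          }
          gwp[wi] = acc_w;
        }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Seeded region growing: breadth-first traversal (FIFO queue) over the
// 4-neighbourhood, admitting unexcluded pixels p with
// |I(p) - I(seed)| <= T. seed_r / seed_c are 1-based.
// [[Rcpp::export]]
LogicalMatrix cpp_grow_region(NumericMatrix img, int seed_r, int seed_c,
                              double T, LogicalMatrix excluded) {
  int H = img.nrow(), W = img.ncol();
  LogicalMatrix region(H, W);
  int sr = seed_r - 1, sc = seed_c - 1;
  double s = img(sr, sc);
  std::queue<int> fifo;
  region(sr, sc) = true;
  fifo.push(sr + H * sc);
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int r = p % H, c = p / H;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (region(rr, cc) || excluded(rr, cc)) continue;
      if (std::fabs(img(rr, cc) - s) <= T) {
        region(rr, cc) = true;
        fifo.push(rr + H * cc);
      }
    }
  }
  return region;
}

// Separable Gaussian blur with border renormalisation (kernel radius 3*sigma).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix m, double sigma) {
  int H = m.nrow(), W = m.ncol();
  if (sigma <= 0) return clone(m);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  for (int d = -rad; d <= rad; ++d)
    k[d + rad] = std::exp(-0.5 * d * d / (sigma * sigma));
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0, norm = 0;
      for (int d = std::max(-rad, -i); d <= std::min(rad, H - 1 - i); ++d) {
        acc += k[d + rad] * m(i + d, j);
        norm += k[d + rad];
      }
      tmp(i, j) = acc / norm;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0, norm = 0;
      for (int d = std::max(-rad, -j); d <= std::min(rad, W - 1 - j); ++d) {
        acc += k[d + rad] * tmp(i, j + d);
        norm += k[d + rad];
      }
      out(i, j) = acc / norm;
    }
  return out;
}
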