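// Numeric core: 2-D convolution (im2col + GEMM), 2x2 max pooling, 2x
// bilinear upsampling, displacement-field warping (grid sample), and
// connected-component labeling. Every differentiable op has an explicit
// backward pass; images are R arrays dim c(H, W, C) mapped to arma::cube.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col with border-replication padding (out-of-bounds taps read the
// nearest border pixel, so a spatially constant input stays constant
// through every convolution); column layout (dh, dw, cin) column-major,
// matching weight matrices of dim (k*k*Cin, Cout).
static inline int clampi(int v, int hi) {
  return v < 0 ? 0 : (v > hi ? hi : v);
}

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* cp = cols.colptr(ho + Ho * wo);
      for (int c = 0; c < C; ++c) {
        const double* xs = x.slice_memptr(c);
        for (int dw = 0; dw < k; ++dw) {
          const int wi = clampi(wo * stride + dw - pad, W - 1);
          const double* xc = xs + (size_t)wi * H;
          const int base = k * (dw + k * c);
          for (int dh = 0; dh < k; ++dh)
            cp[dh + base] = xc[clampi(ho * stride + dh - pad, H - 1)];
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int k,
                         int stride, int pad, int Ho, int Wo) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* cp = cols.colptr(ho + Ho * wo);
      for (int c = 0; c < C; ++c) {
        double* xs = x.slice_memptr(c);
        for (int dw = 0; dw < k; ++dw) {
          const int wi = clampi(wo * stride + dw - pad, W - 1);
          double* xc = xs + (size_t)wi * H;
          const int base = k * (dw + k * c);
          for (int dh = 0; dh < k; ++dh)
            xc[clampi(ho * stride + dh - pad, H - 1)] += cp[dh + base];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.n_cols;
  arma::cube y(Ho, Wo, Cout);
  if (k == 1 && stride == 1 && pad == 0) {
    // 1x1 convolution: plain GEMM on the flattened pixel matrix
    const arma::mat X((double*)x.memptr(), H * W, Cin);
    arma::mat ym = X * w;               // (H*W, Cout)
    ym.each_row() += b.t();
    std::copy(ym.memptr(), ym.memptr() + ym.n_elem, y.memptr());
    return y;
  }
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat ym = cols.t() * w;          // (Ho*Wo, Cout)
  ym.each_row() += b.t();
  std::copy(ym.memptr(), ym.memptr() + ym.n_elem, y.memptr());
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& gy, int k, int stride, int pad,
                    bool want_params = true) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  const arma::mat gym((double*)gy.memptr(), Ho * Wo, Cout);
  if (k == 1 && stride == 1 && pad == 0) {
    const arma::mat X((double*)x.memptr(), H * W, Cin);
    arma::cube gx(H, W, Cin);
    arma::mat gxm = gym * w.t();        // (H*W, Cin)
    std::copy(gxm.memptr(), gxm.memptr() + gxm.n_elem, gx.memptr());
    if (!want_params) return List::create(_["gx"] = gx);
    arma::mat gw = X.t() * gym;
    arma::vec gb = arma::sum(gym, 0).t();
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  arma::mat gcols = w * gym.t();        // (k*k*Cin, Ho*Wo)
  arma::cube gx = col2im(gcols, H, W, Cin, k, stride, pad, Ho, Wo);
  if (!want_params) return List::create(_["gx"] = gx);
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat gw = cols * gym;            // (k*k*Cin, Cout)
  arma::vec gb = arma::sum(gym, 0).t();
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. idx stores the linear index (0-based, within
// the H*W plane of each channel) of the winning element.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        int bi = 2 * ho, bj = 2 * wo;
        double best = x(bi, bj, c); int bh = bi, bw = bj;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = x(bi + di, bj + dj, c);
            if (v > best) { best = v; bh = bi + di; bw = bj + dj; }
          }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = bh + H * bw;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::icube& idx, const arma::cube& gy,
                            int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        long li = idx(ho, wo, c);
        gx(li % H, li / H, c) += gy(ho, wo, c);
      }
  return gx;
}

// 2x bilinear upsampling, half-pixel convention: out(i) samples input at
// (i + 0.5)/2 - 0.5, clamped to the border.
static inline void up2_coef(int i, int n_in, int& i0, int& i1, double& w1) {
  double p = (i + 0.5) / 2.0 - 0.5;
  if (p < 0) p = 0;
  if (p > n_in - 1) p = n_in - 1;
  i0 = (int)std::floor(p);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = p - i0;
}

// [[Rcpp::export]]
arma::cube cpp_up2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::cube y(Ho, Wo, C);
  for (int wo = 0; wo < Wo; ++wo) {
    int j0, j1; double wj;
    up2_coef(wo, W, j0, j1, wj);
    for (int ho = 0; ho < Ho; ++ho) {
      int i0, i1; double wi;
      up2_coef(ho, H, i0, i1, wi);
      for (int c = 0; c < C; ++c)
        y(ho, wo, c) = (1 - wi) * (1 - wj) * x(i0, j0, c)
                     + wi * (1 - wj) * x(i1, j0, c)
                     + (1 - wi) * wj * x(i0, j1, c)
                     + wi * wj * x(i1, j1, c);
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_up2_bwd(const arma::cube& gy, int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    int j0, j1; double wj;
    up2_coef(wo, W, j0, j1, wj);
    for (int ho = 0; ho < Ho; ++ho) {
      int i0, i1; double wi;
      up2_coef(ho, H, i0, i1, wi);
      for (int c = 0; c < C; ++c) {
        double g = gy(ho, wo, c);
        gx(i0, j0, c) += (1 - wi) * (1 - wj) * g;
        gx(i1, j0, c) += wi * (1 - wj) * g;
        gx(i0, j1, c) += (1 - wi) * wj * g;
        gx(i1, j1, c) += wi * wj * g;
      }
    }
  }
  return gx;
}

// Warp (grid sample, gather semantics): out(r,c) = x(r + dy(r,c), c + dx(r,c))
// by bilinear interpolation; out-of-bounds coordinates are clamped to the
// border (replication).
// [[Rcpp::export]]
arma::cube cpp_warp_fwd(const arma::cube& x, const arma::mat& dy,
                        const arma::mat& dx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H, W, C);
  for (int c2 = 0; c2 < W; ++c2)
    for (int r = 0; r < H; ++r) {
      double pr = r + dy(r, c2), pc = c2 + dx(r, c2);
      if (pr < 0) pr = 0; if (pr > H - 1) pr = H - 1;
      if (pc < 0) pc = 0; if (pc > W - 1) pc = W - 1;
      int r0 = (int)std::floor(pr), c0 = (int)std::floor(pc);
      int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      double ar = pr - r0, ac = pc - c0;
      for (int ch = 0; ch < C; ++ch)
        y(r, c2, ch) = (1 - ar) * (1 - ac) * x(r0, c0, ch)
                     + ar * (1 - ac) * x(r1, c0, ch)
                     + (1 - ar) * ac * x(r0, c1, ch)
                     + ar * ac * x(r1, c1, ch);
    }
  return y;
}

// Backward of the warp w.r.t. both the image and the field. At clamped
// coordinates the derivative w.r.t. the field is zero (the clamp is flat).
// [[Rcpp::export]]
List cpp_warp_bwd(const arma::cube& x, const arma::mat& dy,
                  const arma::mat& dx, const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::mat gdy(H, W, arma::fill::zeros), gdx(H, W, arma::fill::zeros);
  for (int c2 = 0; c2 < W; ++c2)
    for (int r = 0; r < H; ++r) {
      double pr = r + dy(r, c2), pc = c2 + dx(r, c2);
      bool in_r = (pr > 0 && pr < H - 1), in_c = (pc > 0 && pc < W - 1);
      if (pr < 0) pr = 0; if (pr > H - 1) pr = H - 1;
      if (pc < 0) pc = 0; if (pc > W - 1) pc = W - 1;
      int r0 = (int)std::floor(pr), c0 = (int)std::floor(pc);
      int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      double ar = pr - r0, ac = pc - c0;
      double sdy = 0, sdx = 0;
      for (int ch = 0; ch < C; ++ch) {
        double g = gy(r, c2, ch);
        gx(r0, c0, ch) += (1 - ar) * (1 - ac) * g;
        gx(r1, c0, ch) += ar * (1 - ac) * g;
        gx(r0, c1, ch) += (1 - ar) * ac * g;
        gx(r1, c1, ch) += ar * ac * g;
        sdy += g * ((1 - ac) * (x(r1, c0, ch) - x(r0, c0, ch))
                  + ac * (x(r1, c1, ch) - x(r0, c1, ch)));
        sdx += g * ((1 - ar) * (x(r0, c1, ch) - x(r0, c0, ch))
                  + ar * (x(r1, c1, ch) - x(r1, c0, ch)));
      }
      if (in_r) gdy(r, c2) = sdy;
      if (in_c) gdx(r, c2) = sdx;
    }
  return List::create(_["gx"] = gx, _["gdy"] = gdy, _["gdx"] = gdx);
}

// Connected-component labeling of a binary mask, 4- or 8-connectivity,
// iterative flood fill; labels assigned in column-major scan order.
// [[Rcpp::export]]
arma::imat cpp_label_components(const arma::imat& mask, int connectivity) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  std::vector<std::pair<int,int>> nb;
  nb.push_back({-1, 0}); nb.push_back({1, 0});
  nb.push_back({0, -1}); nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1});
    nb.push_back({1, -1}); nb.push_back({1, 1});
  }
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto p = stack.back(); stack.pop_back();
        for (auto& d : nb) {
          int rr = p.first + d.first, cc = p.second + d.second;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  return lab;
}
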