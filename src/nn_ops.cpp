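// Minimal dense-prediction CNN primitives: stride-1 'same' convolution via
// im2col + GEMM, 2x2 max pooling, adaptive average pooling, bilinear
// resizing, plus exact backward passes for each.  Tensors are arma::cube
// laid out H x W x C (row, column, channel).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Column order of the patch matrix: index = c*k*k + di*k + dj, so a weight
// matrix is (k*k*Cin) x Cout and the R side only needs consistent shapes.
static mat im2col(const cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * (sword)W, k * k * (sword)C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int col = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int lo = std::max(0, pad - di);
          const int hi = std::min(H, H + pad - di);
          for (int i = lo; i < hi; ++i)
            out(i + (sword)j * H, col) = xs(i + di - pad, sj);
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k, const int pad) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& os = out.slice(c);
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int col = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int lo = std::max(0, pad - di);
          const int hi = std::min(H, H + pad - di);
          for (int i = lo; i < hi; ++i)
            os(i + di - pad, sj) += cols(i + (sword)j * H, col);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat y;
  if (k == 1) {
    mat xm(const_cast<double*>(x.memptr()), H * (sword)W, x.n_slices, false);
    y = xm * w;
  } else {
    y = im2col(x, k, pad) * w;
  }
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& x, const arma::mat& w,
                       const arma::cube& gy, const int k, const int pad,
                       const bool need_gx) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  mat g(const_cast<double*>(gy.memptr()), H * (sword)W, gy.n_slices, false);
  mat gw;
  cube gx;
  if (k == 1) {
    mat xm(const_cast<double*>(x.memptr()), H * (sword)W, Cin, false);
    gw = xm.t() * g;
    if (need_gx) {
      mat gxm = g * w.t();
      gx = cube(gxm.memptr(), H, W, Cin);
    }
  } else {
    mat cols = im2col(x, k, pad);
    gw = cols.t() * g;
    if (need_gx) gx = col2im(g * w.t(), H, W, Cin, k, pad);
  }
  vec gb = sum(g, 0).t();
  if (!need_gx) gx = cube(1, 1, 1, fill::zeros);
  return Rcpp::List::create(Rcpp::Named("gw") = gw, Rcpp::Named("gb") = gb,
                            Rcpp::Named("gx") = gx);
}

// [[Rcpp::export]]
Rcpp::List nn_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  cube idx(Ho, Wo, C);  // 0-based linear index into the input slice
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = xs(2 * i, 2 * j);
        int bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            if (xs(2 * i + di, 2 * j + dj) > best) {
              best = xs(2 * i + di, 2 * j + dj);
              bi = 2 * i + di; bj = 2 * j + dj;
            }
        y(i, j, c) = best;
        idx(i, j, c) = (double)(bi + (sword)bj * H);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube nn_maxpool2_bwd(const arma::cube& idx, const arma::cube& gy,
                           const int H, const int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword j = 0; j < gy.n_cols; ++j)
      for (uword i = 0; i < gy.n_rows; ++i)
        gx.slice(c)((uword)idx(i, j, c)) += gy(i, j, c);
  return gx;
}

// PyTorch-style adaptive bins: bin i covers [floor(i*H/g), floor((i+1)*H/g)).
// [[Rcpp::export]]
arma::cube nn_avgpool_adaptive_fwd(const arma::cube& x, const int g) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(g, g, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < g; ++j) {
      const int j0 = (j * W) / g, j1 = ((j + 1) * W) / g;
      for (int i = 0; i < g; ++i) {
        const int i0 = (i * H) / g, i1 = ((i + 1) * H) / g;
        y(i, j, c) = accu(x.slice(c).submat(i0, j0, i1 - 1, j1 - 1)) /
                     ((i1 - i0) * (double)(j1 - j0));
      }
    }
  return y;
}

// [[Rcpp::export]]
arma::cube nn_avgpool_adaptive_bwd(const arma::cube& gy, const int H,
                                   const int W) {
  const int g = gy.n_rows, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < g; ++j) {
      const int j0 = (j * W) / g, j1 = ((j + 1) * W) / g;
      for (int i = 0; i < g; ++i) {
        const int i0 = (i * H) / g, i1 = ((i + 1) * H) / g;
        gx.slice(c).submat(i0, j0, i1 - 1, j1 - 1) +=
            gy(i, j, c) / ((i1 - i0) * (double)(j1 - j0));
      }
    }
  return gx;
}

static inline void bilin_coef(const int n_in, const int n_out, const int i,
                              int& i0, int& i1, double& w1) {
  double s = (i + 0.5) * n_in / (double)n_out - 0.5;
  if (s < 0) s = 0;
  if (s > n_in - 1) s = n_in - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, n_in - 1);
  w1 = s - i0;
}

// [[Rcpp::export]]
arma::cube nn_upsample_bilinear_fwd(const arma::cube& x, const int Ho,
                                    const int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(Ho, Wo, C);
  for (int j = 0; j < Wo; ++j) {
    int j0, j1; double wj;
    bilin_coef(W, Wo, j, j0, j1, wj);
    for (int i = 0; i < Ho; ++i) {
      int i0, i1; double wi;
      bilin_coef(H, Ho, i, i0, i1, wi);
      for (int c = 0; c < C; ++c) {
        const mat& xs = x.slice(c);
        y(i, j, c) = (1 - wi) * (1 - wj) * xs(i0, j0) +
                     wi * (1 - wj) * xs(i1, j0) +
                     (1 - wi) * wj * xs(i0, j1) + wi * wj * xs(i1, j1);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube nn_upsample_bilinear_bwd(const arma::cube& gy, const int H,
                                    const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int j = 0; j < Wo; ++j) {
    int j0, j1; double wj;
    bilin_coef(W, Wo, j, j0, j1, wj);
    for (int i = 0; i < Ho; ++i) {
      int i0, i1; double wi;
      bilin_coef(H, Ho, i, i0, i1, wi);
      for (int c = 0; c < C; ++c) {
        const double g = gy(i, j, c);
        mat& gs = gx.slice(c);
        gs(i0, j0) += (1 - wi) * (1 - wj) * g;
        gs(i1, j0) += wi * (1 - wj) * g;
        gs(i0, j1) += (1 - wi) * wj * g;
        gs(i1, j1) += wi * wj * g;
      }
    }
  }
  return gx;
}
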