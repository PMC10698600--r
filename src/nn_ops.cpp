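// Minimal 2D CNN kernels (im2col convolution, 2x2 max pooling, nearest
// upsampling) used by the slice-wise U-Net, plus a separable 3D Gaussian
// blur shared by the phantom generator and the surface extractor.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col for k x k same-padding convolution; column index j*H + i.
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  mat cols(C * k * k, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int row = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            cols(row, j * H + i) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& dcols, const int H, const int W, const int C,
                   const int k) {
  const int p = k / 2;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int row = c * k * k + di * k + dj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dcols(row, j * H + i);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, const int k, const bool relu) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat cols = im2col(x, k);
  mat out = w * cols;
  out.each_col() += b;
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube y(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = reshape(out.row(c), H, W);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& x, const arma::mat& w, const int k,
                        const bool relu, const arma::cube& y,
                        const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_rows;
  mat dymat(Cout, H * W);
  for (int c = 0; c < Cout; ++c) {
    mat s = dy.slice(c);
    if (relu) s = s % (y.slice(c) > 0);
    dymat.row(c) = vectorise(s).t();
  }
  mat cols = im2col(x, k);
  mat dw = dymat * cols.t();
  vec db = sum(dymat, 1);
  mat dcols = w.t() * dymat;
  cube dx = col2im(dcols, H, W, Cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double a = x(2 * i, 2 * j, c), b = x(2 * i + 1, 2 * j, c);
        const double d = x(2 * i, 2 * j + 1, c), e = x(2 * i + 1, 2 * j + 1, c);
        y(i, j, c) = std::max(std::max(a, b), std::max(d, e));
      }
  return y;
}

// Gradient routed to the first-encountered maximum (deterministic ties).
// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& x, const arma::cube& dy) {
  const int H = dy.n_rows, W = dy.n_cols, C = x.n_slices;
  cube dx(x.n_rows, x.n_cols, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = x(bi, bj, c);
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        dx(bi, bj, c) += dy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        y(i, j, c) = x(i / 2, j / 2, c);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        dx(i / 2, j / 2, c) += dy(i, j, c);
  return dx;
}

static vec gauss_kernel(const double sigma) {
  if (sigma <= 0) return vec({1.0});
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  return k / accu(k);
}

static inline int reflect(int i, const int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur with reflect padding; sigma in voxels per axis.
// [[Rcpp::export]]
arma::cube cpp_gaussian_blur3(const arma::cube& x, const arma::vec& sigma) {
  cube a = x, b(x.n_rows, x.n_cols, x.n_slices);
  const int n1 = x.n_rows, n2 = x.n_cols, n3 = x.n_slices;
  // axis 1
  {
    vec k = gauss_kernel(sigma(0));
    const int r = (k.n_elem - 1) / 2;
    for (int s = 0; s < n3; ++s)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          double acc = 0;
          for (int d = -r; d <= r; ++d)
            acc += k(d + r) * a(reflect(i + d, n1), j, s);
          b(i, j, s) = acc;
        }
    a = b;
  }
  // axis 2
  {
    vec k = gauss_kernel(sigma(1));
    const int r = (k.n_elem - 1) / 2;
    for (int s = 0; s < n3; ++s)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          double acc = 0;
          for (int d = -r; d <= r; ++d)
            acc += k(d + r) * a(i, reflect(j + d, n2), s);
          b(i, j, s) = acc;
        }
    a = b;
  }
  // axis 3
  {
    vec k = gauss_kernel(sigma(2));
    const int r = (k.n_elem - 1) / 2;
    for (int s = 0; s < n3; ++s)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          double acc = 0;
          for (int d = -r; d <= r; ++d)
            acc += k(d + r) * a(i, j, reflect(s + d, n3));
          b(i, j, s) = acc;
        }
  }
  return b;
}
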