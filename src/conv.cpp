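// 2-D convolution primitives for the feature extractor.
// Layout conventions (match R arrays, column-major):
//   activations: cube H x W x C
//   weights:     mat (k*k*Cin) x Cout, flattened from an R array
//                dim c(k, k, Cin, Cout) -- kernel row fastest.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(k) * k * C,
                 arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + dj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * stride + di - pad;
            if (xi < 0 || xi >= H) continue;
            cols(i + static_cast<size_t>(Ho) * j, col) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.n_cols;
  arma::mat y = im2col(x, k, stride, pad, Ho, Wo) * w;
  y.each_row() += b.t();
  // (Ho*Wo) x Cout shares memory layout with cube Ho x Wo x Cout
  return arma::cube(y.memptr(), Ho, Wo, Cout);
}

// Per-channel (instance) normalization of an H x W x C activation.
// [[Rcpp::export]]
List cpp_instnorm_fwd(const arma::cube& x, double eps) {
  const int C = x.n_slices;
  arma::cube y(x.n_rows, x.n_cols, C);
  arma::vec sd(C);
  for (int c = 0; c < C; ++c) {
    const double mu = arma::mean(arma::vectorise(x.slice(c)));
    arma::mat ctr = x.slice(c) - mu;
    const double s = std::sqrt(arma::mean(arma::vectorise(arma::square(ctr))) + eps);
    y.slice(c) = ctr / s;
    sd(c) = s;
  }
  return List::create(_["y"] = y, _["sd"] = sd);
}

// [[Rcpp::export]]
arma::cube cpp_instnorm_bwd(const arma::cube& y, const arma::vec& sd,
                            const arma::cube& dy) {
  const int C = y.n_slices;
  arma::cube dx(y.n_rows, y.n_cols, C);
  for (int c = 0; c < C; ++c) {
    const double mdy = arma::mean(arma::vectorise(dy.slice(c)));
    const double mdyy = arma::mean(arma::vectorise(dy.slice(c) % y.slice(c)));
    dx.slice(c) = (dy.slice(c) - mdy - y.slice(c) * mdyy) / sd(c);
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dy, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat D(const_cast<double*>(dy.memptr()),
              static_cast<size_t>(Ho) * Wo, Cout, false, true);
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat dw = cols.t() * D;
  arma::vec db = arma::sum(D, 0).t();
  arma::mat dcols = D * w.t();  // (Ho*Wo) x (k*k*C)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j * stride + dj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i * stride + di - pad;
            if (xi < 0 || xi >= H) continue;
            dx(xi, xj, c) += dcols(i + static_cast<size_t>(Ho) * j, col);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
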