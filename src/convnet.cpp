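// Minimal convolution / pooling kernels for the ROI classifier.
// Layout: image batches are 4-D arrays dim = (h, w, channels, n), column-major.
// Convolutions are "valid" (no padding), stride 1, square k x k kernels.
// Weight matrix W: (k*k*channels) x filters, patch order (dy, dx, channel).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector &x, int &h, int &w, int &c, int &n) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  h = d[0]; w = d[1]; c = d[2]; n = d[3];
}

static arma::mat patch_matrix(const double *xs, int H, int W, int C, int k) {
  int OH = H - k + 1, OW = W - k + 1;
  arma::mat P(OH * OW, k * k * C);
  for (int ch = 0; ch < C; ++ch) {
    const double *plane = xs + (size_t)ch * H * W;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        int q = dy + dx * k + ch * k * k;
        for (int oc = 0; oc < OW; ++oc) {
          const double *col = plane + (size_t)(oc + dx) * H + dy;
          double *dst = P.colptr(q) + (size_t)oc * OH;
          std::copy(col, col + OH, dst);
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".cpp_conv_forward")]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix W, NumericVector bias) {
  int H, Wd, C, N;
  get_dims4(x, H, Wd, C, N);
  int k = (int)std::lround(std::sqrt((double)W.nrow() / C));
  if (k * k * C != W.nrow()) stop("kernel/channel mismatch");
  int F = W.ncol(), OH = H - k + 1, OW = Wd - k + 1;
  if (OH < 1 || OW < 1) stop("input smaller than kernel");
  arma::mat Wm(W.begin(), W.nrow(), F, false);
  arma::rowvec b(bias.begin(), F);
  NumericVector out((R_xlen_t)OH * OW * F * N);
  out.attr("dim") = IntegerVector::create(OH, OW, F, N);
  for (int s = 0; s < N; ++s) {
    arma::mat P = patch_matrix(x.begin() + (size_t)s * H * Wd * C, H, Wd, C, k);
    arma::mat Y = P * Wm;
    Y.each_row() += b;
    // Y is (OH*OW) x F with row index oh + ow*OH -> matches (OH, OW, F) layout
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)s * OH * OW * F);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_backward")]]
List cpp_conv_backward(NumericVector x, NumericMatrix W, NumericVector dy) {
  int H, Wd, C, N;
  get_dims4(x, H, Wd, C, N);
  int k = (int)std::lround(std::sqrt((double)W.nrow() / C));
  int F = W.ncol(), OH = H - k + 1, OW = Wd - k + 1;
  arma::mat Wm(W.begin(), W.nrow(), F, false);
  arma::mat dW(W.nrow(), F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * Wd * C * N);
  dx.attr("dim") = IntegerVector::create(H, Wd, C, N);
  for (int s = 0; s < N; ++s) {
    arma::mat P = patch_matrix(x.begin() + (size_t)s * H * Wd * C, H, Wd, C, k);
    arma::mat dY(dy.begin() + (size_t)s * OH * OW * F, OH * OW, F, false);
    dW += P.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dP = dY * Wm.t();
    double *dxs = dx.begin() + (size_t)s * H * Wd * C;
    for (int ch = 0; ch < C; ++ch) {
      double *plane = dxs + (size_t)ch * H * Wd;
      for (int dxk = 0; dxk < k; ++dxk) {
        for (int dyk = 0; dyk < k; ++dyk) {
          int q = dyk + dxk * k + ch * k * k;
          for (int oc = 0; oc < OW; ++oc) {
            const double *src = dP.colptr(q) + (size_t)oc * OH;
            double *col = plane + (size_t)(oc + dxk) * H + dyk;
            for (int r = 0; r < OH; ++r) col[r] += src[r];
          }
        }
      }
    }
  }
  NumericMatrix dWout(W.nrow(), F);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2 (floor); idx records the winning input offset
// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cpp_maxpool_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  int OH = H / 2, OW = W / 2;
  NumericVector y((R_xlen_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  IntegerVector idx((R_xlen_t)OH * OW * C * N);
  idx.attr("dim") = IntegerVector::create(OH, OW, C, N);
  const double *xs = x.begin();
  for (int s = 0; s < N; ++s) {
    for (int ch = 0; ch < C; ++ch) {
      size_t base = (size_t)s * H * W * C + (size_t)ch * H * W;
      size_t obase = (size_t)s * OH * OW * C + (size_t)ch * OH * OW;
      for (int oc = 0; oc < OW; ++oc) {
        for (int orr = 0; orr < OH; ++orr) {
          size_t best = base + (size_t)(2 * oc) * H + 2 * orr;
          double bv = xs[best];
          for (int dc = 0; dc < 2; ++dc) {
            for (int dr = 0; dr < 2; ++dr) {
              size_t p = base + (size_t)(2 * oc + dc) * H + 2 * orr + dr;
              if (xs[p] > bv) { bv = xs[p]; best = p; }
            }
          }
          y[obase + (size_t)oc * OH + orr] = bv;
          idx[obase + (size_t)oc * OH + orr] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(IntegerVector idx, NumericVector dy,
                                   IntegerVector in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}
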