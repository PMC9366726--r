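// Layer primitives for the encoder-decoder segmentation network.
// Tensors are R 3-d arrays (H, W, C), column-major. Convolutions are 3x3
// (or 1x1) stride-1 "same" via im2col + GEMM; pooling is 2x2 max, stride 2;
// upsampling is nearest x2. Backward passes mirror each forward exactly, so
// gradients can be checked against finite differences.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  arma::mat cols(H * W, k * k * C);
  for (int ci = 0; ci < C; ++ci) {
    for (int dr = -p; dr <= p; ++dr) {
      for (int dc = -p; dc <= p; ++dc) {
        int j = (ci * k + (dr + p)) * k + (dc + p);
        for (int c = 0; c < W; ++c) {
          int sc = c + dc;
          for (int r = 0; r < H; ++r) {
            int sr = r + dr;
            double v = 0.0;
            if (sr >= 0 && sr < H && sc >= 0 && sc < W) v = x(sr, sc, ci);
            cols(r + c * H, j) = v;
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(arma::cube& gx, const arma::mat& gcols, int k) {
  int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices, p = (k - 1) / 2;
  for (int ci = 0; ci < C; ++ci) {
    for (int dr = -p; dr <= p; ++dr) {
      for (int dc = -p; dc <= p; ++dc) {
        int j = (ci * k + (dr + p)) * k + (dc + p);
        for (int c = 0; c < W; ++c) {
          int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          for (int r = 0; r < H; ++r) {
            int sr = r + dr;
            if (sr < 0 || sr >= H) continue;
            gx(sr, sc, ci) += gcols(r + c * H, j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k) {
  int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  arma::mat cols = im2col(x, k);
  arma::mat y = cols * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(y.col(co), H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& w,
                  const arma::cube& gy, int k) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices, Cout = w.n_cols;
  arma::mat gymat(H * W, Cout);
  for (int co = 0; co < Cout; ++co)
    gymat.col(co) = arma::vectorise(gy.slice(co));
  arma::mat cols = im2col(x, k);
  arma::mat gw = cols.t() * gymat;
  arma::vec gb = arma::sum(gymat, 0).t();
  arma::mat gcols = gymat * w.t();
  arma::cube gx(H, W, C, arma::fill::zeros);
  col2im_add(gx, gcols, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);  // linear (r + c*H) index of the argmax
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        int r0 = 2 * r, c0 = 2 * c;
        double best = x(r0, c0, ci);
        int br = r0, bc = c0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            double v = x(r0 + dr, c0 + dc, ci);
            if (v > best) { best = v; br = r0 + dr; bc = c0 + dc; }
          }
        y(r, c, ci) = best;
        idx[r + c * Ho + ci * Ho * Wo] = br + bc * H;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const IntegerVector& idx, const arma::cube& gy,
                           int H, int W) {
  int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        int lin = idx[r + c * Ho + ci * Ho * Wo];
        gx(lin % H, lin / H, ci) += gy(r, c, ci);
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = x(r, c, ci);
        y(2 * r, 2 * c, ci) = v;
        y(2 * r + 1, 2 * c, ci) = v;
        y(2 * r, 2 * c + 1, ci) = v;
        y(2 * r + 1, 2 * c + 1, ci) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy) {
  int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        gx(r, c, ci) = gy(2 * r, 2 * c, ci) + gy(2 * r + 1, 2 * c, ci) +
                       gy(2 * r, 2 * c + 1, ci) + gy(2 * r + 1, 2 * c + 1, ci);
  return gx;
}
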