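// Compiled kernels for the segmentation network and the ROI pipeline:
// dilated/strided 2-D convolution (im2col + BLAS) with its gradients,
// and 8-connected component labelling for foreground masks.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the im2col matrix for a (H x W x Cin) cube.
// Column q = ki + kj*k + cin*k*k (ki fastest), matching the column-major
// flattening of an R weight array dim (k, k, Cin, Cout).
static arma::mat im2col(const arma::cube& x, int k, int rate, int stride,
                        int pad, int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  arma::mat col(Hout * (arma::uword)Wout, (arma::uword)k * k * Cin,
                arma::fill::zeros);
  for (int cin = 0; cin < Cin; ++cin) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + kj * k + cin * k * k;
        for (int jo = 0; jo < Wout; ++jo) {
          const int j = jo * stride - pad + kj * rate;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Hout; ++io) {
            const int i = io * stride - pad + ki * rate;
            if (i < 0 || i >= H) continue;
            col(io + (arma::uword)jo * Hout, q) = x(i, j, cin);
          }
        }
      }
    }
  }
  return col;
}

static int out_dim(int n, int k, int rate, int stride, int pad) {
  const int span = (k - 1) * rate + 1;
  return (n + 2 * pad - span) / stride + 1;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int rate, int stride,
                      int pad) {
  const int Hout = out_dim(x.n_rows, k, rate, stride, pad);
  const int Wout = out_dim(x.n_cols, k, rate, stride, pad);
  if (Hout < 1 || Wout < 1)
    stop("input smaller than the effective kernel span");
  const int Cout = w.n_cols;
  arma::mat col = im2col(x, k, rate, stride, pad, Hout, Wout);
  arma::mat out = col * w;
  out.each_row() += b.t();
  arma::cube y(Hout, Wout, Cout);
  for (int co = 0; co < Cout; ++co)
    y.slice(co) = arma::reshape(out.col(co), Hout, Wout);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                const arma::cube& gout, int k, int rate, int stride,
                int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Hout = gout.n_rows, Wout = gout.n_cols, Cout = gout.n_slices;
  arma::mat col = im2col(x, k, rate, stride, pad, Hout, Wout);
  arma::mat G(Hout * (arma::uword)Wout, Cout);
  for (int co = 0; co < Cout; ++co)
    G.col(co) = arma::vectorise(gout.slice(co));
  arma::mat gw = col.t() * G;
  arma::vec gb = arma::sum(G, 0).t();
  arma::mat gcol = G * w.t();
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int cin = 0; cin < Cin; ++cin) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + kj * k + cin * k * k;
        for (int jo = 0; jo < Wout; ++jo) {
          const int j = jo * stride - pad + kj * rate;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Hout; ++io) {
            const int i = io * stride - pad + ki * rate;
            if (i < 0 || i >= H) continue;
            gx(i, j, cin) += gcol(io + (arma::uword)jo * Hout, q);
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 8-connected component labelling by flood fill; labels assigned in
// column-major scan order starting at 1. 0 stays background.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
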