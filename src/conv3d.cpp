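#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kernel-3 3D convolution with zero padding on (voxels x channels) feature
// matrices, x index fastest, via im2col + BLAS. Weight layout: row
// (k-1)*cin + c for offset k (dx fastest in {-1,0,1}^3) and input channel
// c; one output column per output channel.

static inline void offset_of(int k, int &dx, int &dy, int &dz) {
  dx = k % 3 - 1; dy = (k / 3) % 3 - 1; dz = k / 9 - 1;
}

static arma::mat im2col3(const arma::mat &X, int P) {
  const int V = P * P * P, cin = X.n_cols;
  arma::mat Xcol(V, 27 * cin, arma::fill::zeros);
  for (int k = 0; k < 27; ++k) {
    int dx, dy, dz;
    offset_of(k, dx, dy, dz);
    const int x0 = std::max(0, -dx), x1 = std::min(P, P - dx);
    const int y0 = std::max(0, -dy), y1 = std::min(P, P - dy);
    const int z0 = std::max(0, -dz), z1 = std::min(P, P - dz);
    const int shift = dx + P * dy + P * P * dz;
    for (int c = 0; c < cin; ++c) {
      const double *src = X.colptr(c);
      double *dst = Xcol.colptr(k * cin + c);
      for (int iz = z0; iz < z1; ++iz)
        for (int iy = y0; iy < y1; ++iy) {
          const int base = P * iy + P * P * iz;
          std::copy(src + base + shift + x0, src + base + shift + x1,
                    dst + base + x0);
        }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat &X, const arma::mat &W,
                        const arma::vec &b, int P) {
  arma::mat Y = im2col3(X, P) * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat &X, const arma::mat &W,
                   const arma::mat &dY, int P) {
  const int V = P * P * P, cin = X.n_cols;
  arma::mat Xcol = im2col3(X, P);
  arma::mat dW = Xcol.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dXcol = dY * W.t();
  arma::mat dX(V, cin, arma::fill::zeros);
  for (int k = 0; k < 27; ++k) {
    int dx, dy, dz;
    offset_of(k, dx, dy, dz);
    const int x0 = std::max(0, -dx), x1 = std::min(P, P - dx);
    const int y0 = std::max(0, -dy), y1 = std::min(P, P - dy);
    const int z0 = std::max(0, -dz), z1 = std::min(P, P - dz);
    const int shift = dx + P * dy + P * P * dz;
    for (int c = 0; c < cin; ++c) {
      double *acc = dX.colptr(c);
      const double *g = dXcol.colptr(k * cin + c);
      for (int iz = z0; iz < z1; ++iz)
        for (int iy = y0; iy < y1; ++iy) {
          const int base = P * iy + P * P * iz;
          for (int ix = x0; ix < x1; ++ix)
            acc[base + shift + ix] += g[base + ix];
        }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
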