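// Hot loops of the 3D convolutional network: im2col/col2im for the 3x3x3
// stencil (zero padding 1, stride 1) and 2x2x2 stride-2 max pooling.
// Feature tensors are (batch * n_voxels) x n_channels matrices, rows
// sample-major with voxels in column-major grid order. im2col column order
// matches the R side: column (0-based) = offset + 27 * channel.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill Xcol ((B*V) x 27*Cin) from x ((B*V) x Cin).
static void im2col_fill(const arma::mat& x, arma::mat& Xcol,
                        const int d1, const int d2, const int d3,
                        const int batch) {
  const int V = d1 * d2 * d3;
  const int cin = x.n_cols;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x.colptr(c);
    for (int o = 0; o < 27; ++o) {
      const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
      double* col = Xcol.colptr(o + 27 * c);
      const int xlo = std::max(0, -dx), xhi = std::min(d1 - 1, d1 - 1 - dx);
      const int ylo = std::max(0, -dy), yhi = std::min(d2 - 1, d2 - 1 - dy);
      const int zlo = std::max(0, -dz), zhi = std::min(d3 - 1, d3 - 1 - dz);
      const int len = std::max(0, xhi - xlo + 1);
      // fill interior by strip copies; zero only the border remainder
      for (int b = 0; b < batch; ++b) {
        const int base = b * V;
        for (int z = 0; z < d3; ++z) {
          const bool zok = z >= zlo && z <= zhi;
          for (int y = 0; y < d2; ++y) {
            double* dst = col + base + d1 * (y + d2 * z);
            if (!zok || y < ylo || y > yhi || len == 0) {
              std::memset(dst, 0, d1 * sizeof(double));
              continue;
            }
            const double* src = xc + base + (xlo + dx) +
              d1 * ((y + dy) + d2 * (z + dz));
            if (xlo > 0) dst[0] = 0.0;
            std::memcpy(dst + xlo, src, len * sizeof(double));
            if (xhi < d1 - 1) dst[d1 - 1] = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
List conv3d_forward_cpp(const arma::mat& x, const arma::mat& W,
                        const arma::vec& bias, const IntegerVector dims,
                        const int batch) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  arma::mat Xcol(x.n_rows, 27 * x.n_cols);
  im2col_fill(x, Xcol, d1, d2, d3, batch);
  arma::mat y = Xcol * W;
  y.each_row() += bias.t();
  return List::create(_["y"] = y);
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(const arma::mat& dy, const arma::mat& x,
                         const arma::mat& W, const IntegerVector dims,
                         const int batch) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int V = d1 * d2 * d3;
  const int cin = x.n_cols;
  arma::mat Xcol(x.n_rows, 27 * cin);
  im2col_fill(x, Xcol, d1, d2, d3, batch);
  arma::mat dW = Xcol.t() * dy;
  arma::vec db = arma::sum(dy, 0).t();
  arma::mat dXcol = dy * W.t();
  arma::mat dx(x.n_rows, cin, arma::fill::zeros);
  // col2im: accumulate each shifted column block back onto the source voxels
  for (int c = 0; c < cin; ++c) {
    double* dxc = dx.colptr(c);
    for (int o = 0; o < 27; ++o) {
      const int dxo = o % 3 - 1, dyo = (o / 3) % 3 - 1, dzo = o / 9 - 1;
      const double* col = dXcol.colptr(o + 27 * c);
      const int xlo = std::max(0, -dxo), xhi = std::min(d1 - 1, d1 - 1 - dxo);
      const int ylo = std::max(0, -dyo), yhi = std::min(d2 - 1, d2 - 1 - dyo);
      const int zlo = std::max(0, -dzo), zhi = std::min(d3 - 1, d3 - 1 - dzo);
      if (xhi < xlo || yhi < ylo || zhi < zlo) continue;
      const int len = xhi - xlo + 1;
      for (int b = 0; b < batch; ++b) {
        const int base = b * V;
        for (int z = zlo; z <= zhi; ++z) {
          for (int y = ylo; y <= yhi; ++y) {
            const int vdst = base + xlo + d1 * (y + d2 * z);
            const int vsrc = base + (xlo + dxo) + d1 * ((y + dyo) + d2 * (z + dzo));
            const double* src = col + vdst;
            double* dst = dxc + vsrc;
            for (int i = 0; i < len; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(const arma::mat& x, const IntegerVector dims,
                         const int batch) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int e1 = std::max(d1 / 2, 1), e2 = std::max(d2 / 2, 1),
            e3 = std::max(d3 / 2, 1);
  const int V = d1 * d2 * d3, Vout = e1 * e2 * e3;
  const int C = x.n_cols;
  arma::mat y(batch * Vout, C);
  arma::imat am(batch * Vout, C);
  const int k1 = d1 >= 2 ? 2 : 1, k2 = d2 >= 2 ? 2 : 1, k3 = d3 >= 2 ? 2 : 1;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    arma::sword* ac = am.colptr(c);
    for (int b = 0; b < batch; ++b) {
      const int ibase = b * V, obase = b * Vout;
      for (int z = 0; z < e3; ++z) {
        for (int yy = 0; yy < e2; ++yy) {
          for (int xx = 0; xx < e1; ++xx) {
            double best = -std::numeric_limits<double>::infinity();
            int besti = -1;
            for (int oz = 0; oz < k3; ++oz)
              for (int oy = 0; oy < k2; ++oy)
                for (int ox = 0; ox < k1; ++ox) {
                  const int idx = ibase + (2 * xx + ox) +
                    d1 * ((2 * yy + oy) + d2 * (2 * z + oz));
                  if (xc[idx] > best) { best = xc[idx]; besti = idx; }
                }
            const int out = obase + xx + e1 * (yy + e2 * z);
            yc[out] = best;
            ac[out] = besti + 1;  // 1-based for the R side
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am,
                      _["dout"] = IntegerVector::create(e1, e2, e3));
}

// [[Rcpp::export(name = ".maxpool_backward")]]
arma::mat maxpool_backward_cpp(const arma::mat& dy, const arma::imat& am,
                               const int n_in) {
  arma::mat dx(n_in, dy.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dy.n_cols; ++c) {
    const double* dyc = dy.colptr(c);
    const arma::sword* ac = am.colptr(c);
    double* dxc = dx.colptr(c);
    for (arma::uword r = 0; r < dy.n_rows; ++r) dxc[ac[r] - 1] += dyc[r];
  }
  return dx;
}
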