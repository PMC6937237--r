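// Numerical kernels: forward pass ops for the convolutional texture-feature
// extractor (im2col + GEMM) and mesh surface area of a binary mask.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-D multi-channel convolution with zero padding.
// input: h x w x cin cube; weights: (kh*kw*cin) x cout with flat index
// ((c*kh + ki)*kw + kj); returns oh x ow x cout cube.
// [[Rcpp::export(name = ".conv2d_forward")]]
arma::cube conv2d_forward(const arma::cube& input, const arma::mat& weights,
                          const arma::vec& bias, int kh, int kw,
                          int stride, int pad) {
  const int h = input.n_rows, w = input.n_cols, cin = input.n_slices;
  const int cout = weights.n_cols;
  const int oh = (h + 2 * pad - kh) / stride + 1;
  const int ow = (w + 2 * pad - kw) / stride + 1;
  arma::mat cols(oh * ow, kh * kw * cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int col = (c * kh + ki) * kw + kj;
        for (int oi = 0; oi < oh; ++oi) {
          const int ii = oi * stride - pad + ki;
          if (ii < 0 || ii >= h) continue;
          for (int oj = 0; oj < ow; ++oj) {
            const int jj = oj * stride - pad + kj;
            if (jj < 0 || jj >= w) continue;
            cols(oi + oh * oj, col) = input(ii, jj, c);
          }
        }
      }
    }
  }
  arma::mat out = cols * weights;           // (oh*ow) x cout
  out.each_row() += bias.t();
  arma::cube res(oh, ow, cout);
  for (int c = 0; c < cout; ++c)
    res.slice(c) = arma::reshape(out.col(c), oh, ow);
  return res;
}

// Max pooling over each slice.
// [[Rcpp::export(name = ".maxpool_forward")]]
arma::cube maxpool_forward(const arma::cube& input, int size, int stride) {
  const int h = input.n_rows, w = input.n_cols, c = input.n_slices;
  const int oh = (h - size) / stride + 1;
  const int ow = (w - size) / stride + 1;
  arma::cube res(oh, ow, c);
  for (int s = 0; s < c; ++s)
    for (int oi = 0; oi < oh; ++oi)
      for (int oj = 0; oj < ow; ++oj)
        res(oi, oj, s) =
            input.slice(s).submat(oi * stride, oj * stride,
                                  oi * stride + size - 1,
                                  oj * stride + size - 1).max();
  return res;
}

namespace {

// Area of the `level` isosurface of the trilinear interpolant inside one
// grid cell, given the 8 corner values. Computed by marching tetrahedra on
// an m^3 subdivision of the cell so the smooth trilinear surface is
// approximated to O(1/m^2).
double cell_area(const double corner[8], double level, double sx, double sy,
                 double sz, int m) {
  // trilinear values on the (m+1)^3 subgrid
  std::vector<double> f((m + 1) * (m + 1) * (m + 1));
  for (int i = 0; i <= m; ++i) {
    const double x = double(i) / m;
    for (int j = 0; j <= m; ++j) {
      const double y = double(j) / m;
      for (int k = 0; k <= m; ++k) {
        const double z = double(k) / m;
        double v = 0.0;
        for (int b = 0; b < 8; ++b) {
          const double wx = (b & 1) ? x : 1.0 - x;
          const double wy = (b & 2) ? y : 1.0 - y;
          const double wz = (b & 4) ? z : 1.0 - z;
          v += corner[b] * wx * wy * wz;
        }
        f[(i * (m + 1) + j) * (m + 1) + k] = v;
      }
    }
  }
  // 6-tetrahedra decomposition of each subcell around the 0-7 diagonal
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double area = 0.0;
  double px[8], py[8], pz[8], fv[8];
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < m; ++k) {
        for (int b = 0; b < 8; ++b) {
          const int ii = i + ((b & 1) ? 1 : 0);
          const int jj = j + ((b & 2) ? 1 : 0);
          const int kk = k + ((b & 4) ? 1 : 0);
          px[b] = sx * double(ii) / m;
          py[b] = sy * double(jj) / m;
          pz[b] = sz * double(kk) / m;
          fv[b] = f[(ii * (m + 1) + jj) * (m + 1) + kk];
        }
        for (int t = 0; t < 6; ++t) {
          const int* v = tets[t];
          int above[4], nab = 0, nbe = 0, bel[4];
          for (int a = 0; a < 4; ++a) {
            if (fv[v[a]] > level) above[nab++] = v[a];
            else bel[nbe++] = v[a];
          }
          if (nab == 0 || nab == 4) continue;
          // edge intersection points between above/below vertex pairs
          double qx[4], qy[4], qz[4];
          int nq = 0;
          auto cut = [&](int a, int b) {
            const double tt = (level - fv[a]) / (fv[b] - fv[a]);
            qx[nq] = px[a] + tt * (px[b] - px[a]);
            qy[nq] = py[a] + tt * (py[b] - py[a]);
            qz[nq] = pz[a] + tt * (pz[b] - pz[a]);
            ++nq;
          };
          auto tri = [&](int a, int b, int c) {
            const double ux = qx[b] - qx[a], uy = qy[b] - qy[a],
                         uz = qz[b] - qz[a];
            const double vx2 = qx[c] - qx[a], vy2 = qy[c] - qy[a],
                         vz2 = qz[c] - qz[a];
            const double cxv = uy * vz2 - uz * vy2;
            const double cyv = uz * vx2 - ux * vz2;
            const double czv = ux * vy2 - uy * vx2;
            area += 0.5 * std::sqrt(cxv * cxv + cyv * cyv + czv * czv);
          };
          if (nab == 1) {
            cut(above[0], bel[0]); cut(above[0], bel[1]); cut(above[0], bel[2]);
            tri(0, 1, 2);
          } else if (nab == 3) {
            cut(bel[0], above[0]); cut(bel[0], above[1]); cut(bel[0], above[2]);
            tri(0, 1, 2);
          } else {  // 2 vs 2: quad
            cut(above[0], bel[0]); cut(above[0], bel[1]);
            cut(above[1], bel[1]); cut(above[1], bel[0]);
            tri(0, 1, 2); tri(0, 2, 3);
          }
        }
      }
  return area;
}

}  // namespace

// Mesh area (mm^2) of the `level` isosurface of the trilinear interpolant
// of a scalar field sampled at voxel centres (field is treated as 0 outside
// the grid, so surfaces always close).
// [[Rcpp::export(name = ".iso_surface_area")]]
double iso_surface_area(const NumericVector& field, const IntegerVector& dim,
                        const NumericVector& spacing, double level = 0.5,
                        int subdiv = 4) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= d1 || j < 0 || j >= d2 || k < 0 || k >= d3) return 0.0;
    return field[i + d1 * (j + d2 * k)];
  };
  double total = 0.0;
  double corner[8];
  for (int i = -1; i < d1; ++i)
    for (int j = -1; j < d2; ++j)
      for (int k = -1; k < d3; ++k) {
        bool above = false, below = false;
        for (int b = 0; b < 8; ++b) {
          corner[b] = at(i + ((b & 1) ? 1 : 0), j + ((b & 2) ? 1 : 0),
                         k + ((b & 4) ? 1 : 0));
          (corner[b] > level ? above : below) = true;
        }
        if (!(above && below)) continue;
        total += cell_area(corner, level, spacing[0], spacing[1], spacing[2],
                           subdiv);
      }
  return total;
}
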