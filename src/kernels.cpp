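// Low-level numeric kernels for the 3D encoder-decoder.
//
// Volumes are dense double arrays in R's column-major layout with dims
// (X, Y, Z, C); a channel is therefore a contiguous block of n = X*Y*Z
// values.  Convolutions are "same"-padded, stride 1, kernel 3x3x3 (the only
// kernel size used in the conv blocks; 1x1x1 heads are plain matrix
// products and handled in R).  The offset-decomposition below performs one
// small GEMM per kernel tap instead of materialising a vol2col matrix,
// which keeps peak memory at ~2 copies of the activation tensor.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Box {
  int x0, x1, y0, y1, z0, z1;  // destination-side valid region, half-open
};

// Valid destination box for kernel offset (dx,dy,dz): voxels whose shifted
// source index stays inside the volume.
inline Box valid_box(int X, int Y, int Z, int dx, int dy, int dz) {
  Box b;
  b.x0 = std::max(0, -dx); b.x1 = std::min(X, X - dx);
  b.y0 = std::max(0, -dy); b.y1 = std::min(Y, Y - dy);
  b.z0 = std::max(0, -dz); b.z1 = std::min(Z, Z - dz);
  return b;
}

// Gather x shifted by (dx,dy,dz) into the preallocated (n x Cin) buffer.
// Rows outside the valid box are zero.
void gather_shifted(const double* x, arma::mat& S,
                    int X, int Y, int Z, int C,
                    int dx, int dy, int dz) {
  S.zeros();
  const Box b = valid_box(X, Y, Z, dx, dy, dz);
  const int n = X * Y * Z;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * n;
    double* sc = S.colptr(c);
    for (int z = b.z0; z < b.z1; ++z) {
      for (int y = b.y0; y < b.y1; ++y) {
        const int dst0 = b.x0 + X * (y + Y * z);
        const int src0 = (b.x0 + dx) + X * ((y + dy) + Y * (z + dz));
        std::copy(xc + src0, xc + src0 + (b.x1 - b.x0), sc + dst0);
      }
    }
  }
}

// Scatter-add G (n x C) shifted by (dx,dy,dz) into dx-gradient buffer.
void scatter_shifted(double* gx, const arma::mat& G,
                     int X, int Y, int Z, int C,
                     int dx, int dy, int dz) {
  const Box b = valid_box(X, Y, Z, dx, dy, dz);
  const int n = X * Y * Z;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * n;
    const double* sc = G.colptr(c);
    for (int z = b.z0; z < b.z1; ++z) {
      for (int y = b.y0; y < b.y1; ++y) {
        const int dst0 = b.x0 + X * (y + Y * z);
        const int src0 = (b.x0 + dx) + X * ((y + dy) + Y * (z + dz));
        const int len = b.x1 - b.x0;
        for (int i = 0; i < len; ++i) gc[src0 + i] += sc[dst0 + i];
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w, NumericVector bias,
                             IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3], Cout = dims[4];
  const int n = X * Y * Z;
  const arma::mat W(const_cast<double*>(w.begin()), 27 * Cin, Cout, false, true);
  NumericVector out((size_t)n * Cout);
  arma::mat Ymat(out.begin(), n, Cout, false, true);
  for (int c = 0; c < Cout; ++c) Ymat.col(c).fill(bias[c]);
  arma::mat S(n, Cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        gather_shifted(x.begin(), S, X, Y, Z, Cin, dx, dy, dz);
        // rows of W for this tap: offset o, all Cin
        arma::mat Wo(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci) Wo.row(ci) = W.row(o + 27 * ci);
        Ymat += S * Wo;
      }
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector gy,
                     IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3], Cout = dims[4];
  const int n = X * Y * Z;
  const arma::mat W(const_cast<double*>(w.begin()), 27 * Cin, Cout, false, true);
  const arma::mat GY(const_cast<double*>(gy.begin()), n, Cout, false, true);

  NumericVector gxv((size_t)n * Cin);
  NumericVector gwv(27 * Cin * Cout);
  arma::mat GW(gwv.begin(), 27 * Cin, Cout, false, true);
  NumericVector gbv(Cout);

  arma::rowvec gb = arma::sum(GY, 0);
  std::copy(gb.begin(), gb.end(), gbv.begin());

  arma::mat S(n, Cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        gather_shifted(x.begin(), S, X, Y, Z, Cin, dx, dy, dz);
        arma::mat GWo = S.t() * GY;                 // Cin x Cout
        for (int ci = 0; ci < Cin; ++ci) GW.row(o + 27 * ci) = GWo.row(ci);
        arma::mat Wo(Cin, Cout);
        for (int ci = 0; ci < Cin; ++ci) Wo.row(ci) = W.row(o + 27 * ci);
        arma::mat G = GY * Wo.t();                  // n x Cin at shifted pos
        scatter_shifted(gxv.begin(), G, X, Y, Z, Cin, dx, dy, dz);
      }
  gxv.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  gwv.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return List::create(_["gx"] = gxv, _["gw"] = gwv, _["gb"] = gbv);
}

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const int no = Xo * Yo * Zo;
  NumericVector out((size_t)no * C);
  IntegerVector idx((size_t)no * C);  // 1-based linear index into x
  const int n = X * Y * Z;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double* oc = out.begin() + (size_t)c * no;
    int* ic = idx.begin() + (size_t)c * no;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int xo = 0; xo < Xo; ++xo) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int si = (2 * xo + dx) + X * ((2 * y + dy) + Y * (2 * z + dz));
                if (xc[si] > best) { best = xc[si]; bi = si; }
              }
          const int oi = xo + Xo * (y + Yo * z);
          oc[oi] = best;
          ic[oi] = bi + 1 + c * n;
        }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward(NumericVector gy, IntegerVector idx,
                                 IntegerVector in_dims) {
  const size_t n_in = (size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector gx(n_in);
  const int m = gy.size();
  for (int i = 0; i < m; ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = in_dims;
  return gx;
}

// [[Rcpp::export(name = ".upsample3d_forward")]]
NumericVector upsample3d_forward(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((size_t)Xo * Yo * Zo * C);
  const int n = X * Y * Z, no = Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double* oc = out.begin() + (size_t)c * no;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int xo = 0; xo < Xo; ++xo)
          oc[xo + Xo * (y + Yo * z)] =
            xc[(xo / 2) + X * ((y / 2) + Y * (z / 2))];
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return out;
}

// [[Rcpp::export(name = ".upsample3d_backward")]]
NumericVector upsample3d_backward(NumericVector gy, IntegerVector out_dims) {
  const int Xo = out_dims[0], Yo = out_dims[1], Zo = out_dims[2], C = out_dims[3];
  const int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
  NumericVector gx((size_t)X * Y * Z * C);
  const int n = X * Y * Z, no = Xo * Yo * Zo;
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + (size_t)c * no;
    double* oc = gx.begin() + (size_t)c * n;
    for (int z = 0; z < Zo; ++z)
      for (int y = 0; y < Yo; ++y)
        for (int xo = 0; xo < Xo; ++xo)
          oc[(xo / 2) + X * ((y / 2) + Y * (z / 2))] +=
            gc[xo + Xo * (y + Yo * z)];
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return gx;
}

// Majority-vote label downsampling by factor 2 per axis.  Ties break toward
// the smaller label id so the result is deterministic.
// [[Rcpp::export(name = ".label_downsample2")]]
IntegerVector label_downsample2(IntegerVector lab, IntegerVector dims, int n_labels) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  IntegerVector out((size_t)Xo * Yo * Zo);
  std::vector<int> count(n_labels);
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xo = 0; xo < Xo; ++xo) {
        std::fill(count.begin(), count.end(), 0);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              ++count[lab[(2 * xo + dx) + X * ((2 * y + dy) + Y * (2 * z + dz))]];
        int best = 0;
        for (int l = 1; l < n_labels; ++l) if (count[l] > count[best]) best = l;
        out[xo + Xo * (y + Yo * z)] = best;
      }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  return out;
}

// --- batchnorm / relu / blur helpers ------------------------------------

// [[Rcpp::export(name = ".channel_stats")]]
List channel_stats_cpp(NumericVector x, IntegerVector dims) {
  const int n = dims[0] * dims[1] * dims[2], C = dims[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mean[c] = s / n;
    double v = s2 / n - mean[c] * mean[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_apply")]]
List bn_apply(NumericVector x, NumericVector mean, NumericVector invstd,
              NumericVector gamma, NumericVector beta, IntegerVector dims) {
  const int n = dims[0] * dims[1] * dims[2], C = dims[3];
  NumericVector y(x.size()), xhat(x.size());
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)c * n;
    double* yc = y.begin() + (size_t)c * n;
    double* hc = xhat.begin() + (size_t)c * n;
    const double m = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
    for (int i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  y.attr("dim") = dims;
  xhat.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// [[Rcpp::export(name = ".bn_grad")]]
List bn_grad(NumericVector gy, NumericVector xhat, NumericVector gamma,
             NumericVector invstd, IntegerVector dims, bool batch) {
  const int n = dims[0] * dims[1] * dims[2], C = dims[3];
  NumericVector gx(gy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* gc = gy.begin() + (size_t)c * n;
    const double* hc = xhat.begin() + (size_t)c * n;
    double* oc = gx.begin() + (size_t)c * n;
    double sg = 0, sgh = 0;
    for (int i = 0; i < n; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    dgamma[c] = sgh;
    dbeta[c] = sg;
    const double k = gamma[c] * invstd[c];
    if (batch) {
      const double mg = sg / n, mgh = sgh / n;
      for (int i = 0; i < n; ++i) oc[i] = k * (gc[i] - mg - hc[i] * mgh);
    } else {
      for (int i = 0; i < n; ++i) oc[i] = k * gc[i];
    }
  }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_forward")]]
NumericVector relu_forward_cpp(NumericVector x) {
  NumericVector y = clone(x);
  for (double& v : y) if (v < 0) v = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".relu_backward")]]
NumericVector relu_backward_cpp(NumericVector gy, NumericVector y) {
  NumericVector gx = clone(gy);
  for (int i = 0; i < gx.size(); ++i) if (y[i] <= 0) gx[i] = 0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// Separable blur along one axis of a (X, Y, Z, C) array with a normalized
// kernel, renormalizing at the edges (reflection-free truncation).
static void blur_axis_cpp(const double* x, double* y, int nx, int stride,
                          int nrep_inner, int nrep_outer, int outer_stride,
                          const std::vector<double>& k, int r) {
  for (int o = 0; o < nrep_outer; ++o)
    for (int in = 0; in < nrep_inner; ++in) {
      const double* xs = x + (size_t)o * outer_stride + in;
      double* ys = y + (size_t)o * outer_stride + in;
      for (int i = 0; i < nx; ++i) {
        double acc = 0, wsum = 0;
        const int j0 = std::max(0, i - r), j1 = std::min(nx - 1, i + r);
        for (int j = j0; j <= j1; ++j) {
          const double w = k[j - i + r];
          acc += w * xs[(size_t)j * stride];
          wsum += w;
        }
        ys[(size_t)i * stride] = acc / wsum;
      }
    }
}

// [[Rcpp::export(name = ".gaussian_blur3d")]]
NumericVector gaussian_blur3d_cpp(NumericVector x, IntegerVector dims,
                                  double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int C = dims.size() > 3 ? dims[3] : 1;
  const int r = std::max(1, (int)std::ceil(3 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  NumericVector a = clone(x), b(x.size());
  const int n = X * Y * Z;
  // axis 1 (x): stride 1, inner reps 1 grouped: iterate outer = Y*Z*C
  blur_axis_cpp(a.begin(), b.begin(), X, 1, 1, Y * Z * C, X, k, r);
  // axis 2 (y): stride X, inner X, outer Z*C with stride X*Y
  blur_axis_cpp(b.begin(), a.begin(), Y, X, X, Z * C, X * Y, k, r);
  // axis 3 (z): stride X*Y, inner X*Y, outer C with stride n
  blur_axis_cpp(a.begin(), b.begin(), Z, X * Y, X * Y, C, n, k, r);
  b.attr("dim") = x.attr("dim");
  return b;
}
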