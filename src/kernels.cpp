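// Low-level numerical kernels: 3D convolution (im2col + GEMM) with stride and
// dilation, nearest-neighbour up/down-sampling, trilinear/nearest warping,
// separable Gaussian smoothing, slice-wise bilateral filtering, and a flood
// fill used for connectivity checks on phantom masks.
//
// Array convention throughout: R's column-major order with dims
// (rows, cols, slices[, channels]); rows vary fastest.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int ceil_div(int a, int b) { return (a + b - 1) / b; }

// "same" padding before the first element so that out = ceil(in / stride)
static inline int pad_lo(int in, int out, int stride, int k, int dil) {
  int tot = (out - 1) * stride + (k - 1) * dil + 1 - in;
  if (tot < 0) tot = 0;
  return tot / 2;
}

// Valid output-index range [lo, hi] for one kernel tap along one axis:
// 0 <= o*stride - pad + tap*dil <= in-1, clipped to [0, out-1].
static inline void tap_range(int in, int out, int stride, int pad, int off,
                             int& lo, int& hi) {
  lo = (pad - off + stride - 1) / stride;
  if (lo < 0) lo = 0;
  hi = (in - 1 + pad - off) / stride;
  if (hi > out - 1) hi = out - 1;
}

// Fill the im2col matrix for output slices [s0, s0+ns): one row per output
// voxel, one column per (input channel, kernel tap) pair.
// Column index = ci * k^3 + (kr * k + kc) * k + ks.
static void im2col_chunk(const double* x, int R, int C, int S, int Cin,
                         int Rout, int Cout, int k,
                         int sr, int sc, int ss, int dil,
                         int pr, int pc, int ps,
                         int s0, int ns, arma::mat& M) {
  const int vol = R * C * S;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * vol;
    for (int kr = 0; kr < k; ++kr) {
      int rlo, rhi;
      tap_range(R, Rout, sr, pr, kr * dil, rlo, rhi);
      for (int kc = 0; kc < k; ++kc) {
        int clo, chi;
        tap_range(C, Cout, sc, pc, kc * dil, clo, chi);
        for (int ks = 0; ks < k; ++ks) {
          const int col = ci * k * k * k + (kr * k + kc) * k + ks;
          double* Mcol = M.colptr(col);
          for (int osl = 0; osl < ns; ++osl) {
            const int is = (s0 + osl) * ss - ps + ks * dil;
            double* Mslab = Mcol + (size_t)Cout * osl * Rout;
            if (is < 0 || is >= S) {
              std::fill(Mslab, Mslab + (size_t)Cout * Rout, 0.0);
              continue;
            }
            for (int oc = 0; oc < Cout; ++oc) {
              const int ic = oc * sc - pc + kc * dil;
              double* Mrow = Mslab + (size_t)oc * Rout;
              if (ic < 0 || ic >= C || oc < clo || oc > chi) {
                std::fill(Mrow, Mrow + Rout, 0.0);
                continue;
              }
              const double* xcol = xc + (size_t)(ic + C * is) * R;
              for (int orow = 0; orow < rlo; ++orow) Mrow[orow] = 0.0;
              if (sr == 1) {
                const int ir0 = rlo - pr + kr * dil;
                std::copy(xcol + ir0, xcol + ir0 + (rhi - rlo + 1), Mrow + rlo);
              } else {
                int ir = rlo * sr - pr + kr * dil;
                for (int orow = rlo; orow <= rhi; ++orow, ir += sr)
                  Mrow[orow] = xcol[ir];
              }
              for (int orow = rhi + 1; orow < Rout; ++orow) Mrow[orow] = 0.0;
            }
          }
        }
      }
    }
  }
}

// Choose how many output slices fit a ~64 MB im2col chunk.
static int chunk_slices(int Rout, int Cout, int ncolM, int Sout) {
  double per_slice = (double)Rout * Cout * ncolM;
  int ns = (int)std::floor(8.0e6 / std::max(per_slice, 1.0));
  if (ns < 1) ns = 1;
  if (ns > Sout) ns = Sout;
  return ns;
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(const NumericVector& x, const IntegerVector& xdim,
                                 const arma::mat& W, const arma::vec& b,
                                 int k, const IntegerVector& stride, int dilation) {
  const int R = xdim[0], C = xdim[1], S = xdim[2], Cin = xdim[3];
  const int sr = stride[0], sc = stride[1], ss = stride[2];
  const int Rout = ceil_div(R, sr), Cout = ceil_div(C, sc), Sout = ceil_div(S, ss);
  const int pr = pad_lo(R, Rout, sr, k, dilation);
  const int pc = pad_lo(C, Cout, sc, k, dilation);
  const int ps = pad_lo(S, Sout, ss, k, dilation);
  const int Cf = W.n_cols;
  const size_t Vout = (size_t)Rout * Cout * Sout;
  NumericVector y((R_xlen_t)(Vout * Cf));

  const int nsmax = chunk_slices(Rout, Cout, W.n_rows, Sout);
  arma::mat M((size_t)Rout * Cout * nsmax, W.n_rows);
  for (int s0 = 0; s0 < Sout; s0 += nsmax) {
    const int ns = std::min(nsmax, Sout - s0);
    arma::mat Mv = M.rows(0, (size_t)Rout * Cout * ns - 1);
    im2col_chunk(REAL(x), R, C, S, Cin, Rout, Cout, k, sr, sc, ss, dilation,
                 pr, pc, ps, s0, ns, Mv);
    arma::mat Y = Mv * W;
    for (int f = 0; f < Cf; ++f) {
      double* yp = REAL(y) + (size_t)f * Vout + (size_t)Rout * Cout * s0;
      const double* Yp = Y.colptr(f);
      const double bf = b[f];
      const size_t n = (size_t)Rout * Cout * ns;
      for (size_t i = 0; i < n; ++i) yp[i] = Yp[i] + bf;
    }
  }
  y.attr("dim") = IntegerVector::create(Rout, Cout, Sout, Cf);
  return y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(const NumericVector& x, const IntegerVector& xdim,
                         const arma::mat& W, int k, const IntegerVector& stride,
                         int dilation, const NumericVector& dy) {
  const int R = xdim[0], C = xdim[1], S = xdim[2], Cin = xdim[3];
  const int sr = stride[0], sc = stride[1], ss = stride[2];
  const int Rout = ceil_div(R, sr), Cout = ceil_div(C, sc), Sout = ceil_div(S, ss);
  const int pr = pad_lo(R, Rout, sr, k, dilation);
  const int pc = pad_lo(C, Cout, sc, k, dilation);
  const int ps = pad_lo(S, Sout, ss, k, dilation);
  const int Cf = W.n_cols;
  const size_t Vout = (size_t)Rout * Cout * Sout;

  NumericVector dx((R_xlen_t)((size_t)R * C * S * Cin));
  arma::mat dW(W.n_rows, Cf, arma::fill::zeros);
  arma::vec db(Cf, arma::fill::zeros);

  const int nsmax = chunk_slices(Rout, Cout, W.n_rows, Sout);
  arma::mat M((size_t)Rout * Cout * nsmax, W.n_rows);
  const int vol = R * C * S;

  for (int s0 = 0; s0 < Sout; s0 += nsmax) {
    const int ns = std::min(nsmax, Sout - s0);
    const size_t nrow = (size_t)Rout * Cout * ns;
    arma::mat Mv = M.rows(0, nrow - 1);
    im2col_chunk(REAL(x), R, C, S, Cin, Rout, Cout, k, sr, sc, ss, dilation,
                 pr, pc, ps, s0, ns, Mv);
    arma::mat dYc(nrow, Cf);
    for (int f = 0; f < Cf; ++f) {
      const double* dyp = REAL(dy) + (size_t)f * Vout + (size_t)Rout * Cout * s0;
      std::copy(dyp, dyp + nrow, dYc.colptr(f));
    }
    dW += Mv.t() * dYc;
    db += arma::sum(dYc, 0).t();
    arma::mat dM = dYc * W.t();
    // scatter-add dM back onto dx (reverse of im2col)
    for (int ci = 0; ci < Cin; ++ci) {
      double* dxc = REAL(dx) + (size_t)ci * vol;
      for (int kr = 0; kr < k; ++kr) {
        int rlo, rhi;
        tap_range(R, Rout, sr, pr, kr * dilation, rlo, rhi);
        for (int kc = 0; kc < k; ++kc) {
          int clo, chi;
          tap_range(C, Cout, sc, pc, kc * dilation, clo, chi);
          for (int ks = 0; ks < k; ++ks) {
            const int col = ci * k * k * k + (kr * k + kc) * k + ks;
            const double* Dcol = dM.colptr(col);
            for (int osl = 0; osl < ns; ++osl) {
              const int is = (s0 + osl) * ss - ps + ks * dilation;
              if (is < 0 || is >= S) continue;
              for (int oc = clo; oc <= chi; ++oc) {
                const int ic = oc * sc - pc + kc * dilation;
                double* dxcol = dxc + (size_t)(ic + C * is) * R;
                const double* Drow = Dcol + (size_t)(oc + Cout * osl) * Rout;
                if (sr == 1) {
                  const int ir0 = rlo - pr + kr * dilation;
                  for (int orow = rlo; orow <= rhi; ++orow)
                    dxcol[ir0 + orow - rlo] += Drow[orow];
                } else {
                  int ir = rlo * sr - pr + kr * dilation;
                  for (int orow = rlo; orow <= rhi; ++orow, ir += sr)
                    dxcol[ir] += Drow[orow];
                }
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(R, C, S, Cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector upsample_nn_cpp(const NumericVector& x, const IntegerVector& xdim,
                              const IntegerVector& factor, const IntegerVector& outdim) {
  const int R = xdim[0], C = xdim[1], S = xdim[2], Ch = xdim[3];
  const int Ro = outdim[0], Co = outdim[1], So = outdim[2];
  NumericVector y((R_xlen_t)((size_t)Ro * Co * So * Ch));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int ch = 0; ch < Ch; ++ch) {
    const double* xc = xp + (size_t)ch * R * C * S;
    double* yc = yp + (size_t)ch * Ro * Co * So;
    for (int s = 0; s < So; ++s) {
      const int is = std::min(s / factor[2], S - 1);
      for (int c = 0; c < Co; ++c) {
        const int ic = std::min(c / factor[1], C - 1);
        const double* xcol = xc + (size_t)(ic + C * is) * R;
        double* ycol = yc + (size_t)(c + Co * s) * Ro;
        for (int r = 0; r < Ro; ++r)
          ycol[r] = xcol[std::min(r / factor[0], R - 1)];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ro, Co, So, Ch);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_nn_backward_cpp(const NumericVector& dy, const IntegerVector& ydim,
                                       const IntegerVector& factor, const IntegerVector& indim) {
  const int Ro = ydim[0], Co = ydim[1], So = ydim[2], Ch = ydim[3];
  const int R = indim[0], C = indim[1], S = indim[2];
  NumericVector dx((R_xlen_t)((size_t)R * C * S * Ch));
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int ch = 0; ch < Ch; ++ch) {
    const double* yc = dyp + (size_t)ch * Ro * Co * So;
    double* xc = dxp + (size_t)ch * R * C * S;
    for (int s = 0; s < So; ++s) {
      const int is = std::min(s / factor[2], S - 1);
      for (int c = 0; c < Co; ++c) {
        const int ic = std::min(c / factor[1], C - 1);
        double* xcol = xc + (size_t)(ic + C * is) * R;
        const double* ycol = yc + (size_t)(c + Co * s) * Ro;
        for (int r = 0; r < Ro; ++r)
          xcol[std::min(r / factor[0], R - 1)] += ycol[r];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(R, C, S, Ch);
  return dx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Sample x at fractional source coordinates (cr, cc, cs), one per output
// voxel (0-based). Coordinates clamped to the volume; nearest = true uses
// nearest-neighbour, else trilinear.
// [[Rcpp::export]]
NumericVector warp_cpp(const NumericVector& x, const IntegerVector& xdim,
                       const NumericVector& cr, const NumericVector& cc,
                       const NumericVector& cs, bool nearest) {
  const int R = xdim[0], C = xdim[1], S = xdim[2];
  const R_xlen_t n = cr.size();
  NumericVector y(n);
  const double* xp = REAL(x);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = clampd(cr[i], 0.0, R - 1.0);
    double c = clampd(cc[i], 0.0, C - 1.0);
    double s = clampd(cs[i], 0.0, S - 1.0);
    if (nearest) {
      int ir = (int)std::lround(r), ic = (int)std::lround(c), is = (int)std::lround(s);
      y[i] = xp[ir + (size_t)(ic + C * is) * R];
    } else {
      int r0 = (int)std::floor(r), c0 = (int)std::floor(c), s0 = (int)std::floor(s);
      int r1 = std::min(r0 + 1, R - 1), c1 = std::min(c0 + 1, C - 1), s1 = std::min(s0 + 1, S - 1);
      double fr = r - r0, fc = c - c0, fs = s - s0;
      double v = 0.0;
      for (int dr = 0; dr <= 1; ++dr)
        for (int dc = 0; dc <= 1; ++dc)
          for (int ds = 0; ds <= 1; ++ds) {
            double w = (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc) * (ds ? fs : 1 - fs);
            if (w == 0.0) continue;
            int ir = dr ? r1 : r0, ic = dc ? c1 : c0, is = ds ? s1 : s0;
            v += w * xp[ir + (size_t)(ic + C * is) * R];
          }
      y[i] = v;
    }
  }
  return y;
}

static void smooth_axis(std::vector<double>& v, int R, int C, int S,
                        const std::vector<double>& w, int axis) {
  const int rad = (int)(w.size() - 1) / 2;
  std::vector<double> out(v.size());
  const int dims[3] = {R, C, S};
  const int len = dims[axis];
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < C; ++c)
      for (int r = 0; r < R; ++r) {
        const int idx3[3] = {r, c, s};
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t) {
          int p = idx3[axis] + t;
          if (p < 0) p = 0;
          if (p >= len) p = len - 1;
          int rr = r, cc = c, ss = s;
          if (axis == 0) rr = p; else if (axis == 1) cc = p; else ss = p;
          acc += w[t + rad] * v[rr + (size_t)(cc + C * ss) * R];
        }
        out[r + (size_t)(c + C * s) * R] = acc;
      }
  v.swap(out);
}

// [[Rcpp::export]]
NumericVector gauss_smooth3_cpp(const NumericVector& x, const IntegerVector& dims,
                                double sigma) {
  const int R = dims[0], C = dims[1], S = dims[2];
  std::vector<double> v(REAL(x), REAL(x) + (size_t)R * C * S);
  if (sigma > 0) {
    int rad = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * rad + 1);
    double tot = 0.0;
    for (int t = -rad; t <= rad; ++t) {
      w[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
      tot += w[t + rad];
    }
    for (double& wi : w) wi /= tot;
    for (int axis = 0; axis < 3; ++axis) smooth_axis(v, R, C, S, w, axis);
  }
  NumericVector y(v.begin(), v.end());
  y.attr("dim") = IntegerVector::create(R, C, S);
  return y;
}

// Slice-wise 2D bilateral filter over a (rows, cols, slices) volume.
// [[Rcpp::export]]
NumericVector bilateral2d_cpp(const NumericVector& x, const IntegerVector& dims,
                              double sigma_spatial, double sigma_intensity) {
  const int R = dims[0], C = dims[1], S = dims[2];
  const int rad = std::max(1, (int)std::ceil(2.0 * sigma_spatial));
  NumericVector y((R_xlen_t)((size_t)R * C * S));
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double is2 = 1.0 / (2.0 * sigma_spatial * sigma_spatial);
  const double ii2 = 1.0 / (2.0 * sigma_intensity * sigma_intensity);
  std::vector<double> sw((2 * rad + 1) * (2 * rad + 1));
  for (int dr = -rad; dr <= rad; ++dr)
    for (int dc = -rad; dc <= rad; ++dc)
      sw[(dr + rad) * (2 * rad + 1) + dc + rad] = std::exp(-(dr * dr + dc * dc) * is2);
  for (int s = 0; s < S; ++s) {
    const double* xs = xp + (size_t)R * C * s;
    double* ys = yp + (size_t)R * C * s;
    for (int c = 0; c < C; ++c)
      for (int r = 0; r < R; ++r) {
        const double v0 = xs[r + (size_t)c * R];
        double acc = 0.0, wsum = 0.0;
        for (int dc = -rad; dc <= rad; ++dc) {
          const int cc = c + dc;
          if (cc < 0 || cc >= C) continue;
          for (int dr = -rad; dr <= rad; ++dr) {
            const int rr = r + dr;
            if (rr < 0 || rr >= R) continue;
            const double v = xs[rr + (size_t)cc * R];
            const double d = v - v0;
            const double w = sw[(dr + rad) * (2 * rad + 1) + dc + rad] *
                             std::exp(-d * d * ii2);
            acc += w * v;
            wsum += w;
          }
        }
        ys[r + (size_t)c * R] = acc / wsum;
      }
  }
  y.attr("dim") = IntegerVector::create(R, C, S);
  return y;
}

// Batch/instance normalization over all voxels, per channel.
// [[Rcpp::export]]
List bn_forward_cpp(const NumericVector& x, const IntegerVector& dims,
                    const arma::vec& gamma, const arma::vec& beta, double eps) {
  const size_t n = (size_t)dims[0] * dims[1] * dims[2];
  const int ch = dims[3];
  NumericVector y(x.size());
  arma::vec mu(ch), invstd(ch);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < ch; ++c) {
    const double* xc = xp + (size_t)c * n;
    double s = 0.0, s2 = 0.0;
    for (size_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    mu[c] = m;
    invstd[c] = 1.0 / std::sqrt(v + eps);
    const double a = gamma[c] * invstd[c];
    const double b = beta[c] - a * m;
    double* yc = yp + (size_t)c * n;
    for (size_t i = 0; i < n; ++i) yc[i] = a * xc[i] + b;
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["mu"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_backward_cpp(const NumericVector& x, const IntegerVector& dims,
                     const arma::vec& gamma, const arma::vec& mu,
                     const arma::vec& invstd, const NumericVector& dy) {
  const size_t n = (size_t)dims[0] * dims[1] * dims[2];
  const int ch = dims[3];
  NumericVector dx(x.size());
  arma::vec dgamma(ch), dbeta(ch);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int c = 0; c < ch; ++c) {
    const double* xc = xp + (size_t)c * n;
    const double* dyc = dyp + (size_t)c * n;
    double* dxc = dxp + (size_t)c * n;
    const double m = mu[c], is = invstd[c];
    double sg = 0.0, sb = 0.0;
    for (size_t i = 0; i < n; ++i) {
      const double xhat = (xc[i] - m) * is;
      sg += dyc[i] * xhat;
      sb += dyc[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c];
    const double t1 = sb / n, t2 = sg / n;
    for (size_t i = 0; i < n; ++i) {
      const double xhat = (xc[i] - m) * is;
      dxc[i] = (g * dyc[i] - g * t1 - g * xhat * t2) * is;
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// PReLU with one learnable slope per channel.
// [[Rcpp::export]]
NumericVector prelu_forward_cpp(const NumericVector& x, const IntegerVector& dims,
                                const arma::vec& alpha) {
  const size_t n = (size_t)dims[0] * dims[1] * dims[2];
  const int ch = dims[3];
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < ch; ++c) {
    const double a = alpha[c];
    const double* xc = xp + (size_t)c * n;
    double* yc = yp + (size_t)c * n;
    for (size_t i = 0; i < n; ++i) yc[i] = xc[i] >= 0 ? xc[i] : a * xc[i];
  }
  y.attr("dim") = dims;
  return y;
}

// [[Rcpp::export]]
List prelu_backward_cpp(const NumericVector& x, const IntegerVector& dims,
                        const arma::vec& alpha, const NumericVector& dy) {
  const size_t n = (size_t)dims[0] * dims[1] * dims[2];
  const int ch = dims[3];
  NumericVector dx(x.size());
  arma::vec dalpha(ch);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int c = 0; c < ch; ++c) {
    const double a = alpha[c];
    const double* xc = xp + (size_t)c * n;
    const double* dyc = dyp + (size_t)c * n;
    double* dxc = dxp + (size_t)c * n;
    double da = 0.0;
    for (size_t i = 0; i < n; ++i) {
      if (xc[i] >= 0) dxc[i] = dyc[i];
      else { dxc[i] = a * dyc[i]; da += dyc[i] * xc[i]; }
    }
    dalpha[c] = da;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dalpha"] = dalpha);
}

// Size of the 26-connected component containing the first nonzero voxel.
// [[Rcpp::export]]
int flood_count_cpp(const LogicalVector& mask, const IntegerVector& dims) {
  const int R = dims[0], C = dims[1], S = dims[2];
  const size_t n = (size_t)R * C * S;
  const int* mp = LOGICAL(mask);
  std::vector<char> seen(n, 0);
  size_t start = n;
  for (size_t i = 0; i < n; ++i)
    if (mp[i] == TRUE) { start = i; break; }
  if (start == n) return 0;
  std::vector<int> stack;
  stack.push_back((int)start);
  seen[start] = 1;
  int count = 0;
  while (!stack.empty()) {
    const int idx = stack.back();
    stack.pop_back();
    ++count;
    const int r = idx % R, c = (idx / R) % C, s = idx / (R * C);
    for (int ds = -1; ds <= 1; ++ds)
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (!dr && !dc && !ds) continue;
          const int rr = r + dr, cc = c + dc, ss = s + ds;
          if (rr < 0 || rr >= R || cc < 0 || cc >= C || ss < 0 || ss >= S) continue;
          const size_t j = rr + (size_t)(cc + C * ss) * R;
          if (mp[j] == TRUE && !seen[j]) {
            seen[j] = 1;
            stack.push_back((int)j);
          }
        }
  }
  return count;
}
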