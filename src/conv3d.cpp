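// 3D valid convolution via slab-wise im2col + gemm.
// Single-precision path for speed (bandwidth-bound skinny gemms); double path
// retained for finite-difference gradient checks.
// Array layouts are R column-major: x[X,Y,Z,Cin], W[kx,ky,kz,Cin,Cout],
// out[ox,oy,oz,Cout] with o = X - k + 1 (valid padding).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double SLAB_BYTES = 64.0 * 1024 * 1024;

// Workspace: the im2col slab matrices built during a forward pass, kept so
// the matching backward pass can skip rebuilding them.
template <typename eT>
struct ConvWS {
  std::vector<arma::Mat<eT> > slabs;
};

// Fill M (n_slab x K) with input windows for output z-slices [z0, z0+zn).
// Column order: ii fastest, then jj, kk, c — identical to W's memory order,
// so W reshapes to (K x Cout) without permutation.
template <typename MT>
static void im2col_slab(const double* x, const IntegerVector& xd,
                        const IntegerVector& kd, const int* od,
                        int z0, int zn, MT& M) {
  const int ox = od[0], oy = od[1];
  const int X = xd[0], Y = xd[1];
  const long XY = (long)X * Y, XYZ = XY * xd[2];
  long col = 0;
  for (int c = 0; c < xd[3]; ++c)
    for (int kk = 0; kk < kd[2]; ++kk)
      for (int jj = 0; jj < kd[1]; ++jj)
        for (int ii = 0; ii < kd[0]; ++ii) {
          typename MT::elem_type* mcol = M.colptr(col);
          long mi = 0;
          for (int z = z0; z < z0 + zn; ++z) {
            const double* base = x + c * XYZ + (long)(z + kk) * XY;
            for (int j = 0; j < oy; ++j) {
              const double* row = base + (long)(j + jj) * X + ii;
              for (int i = 0; i < ox; ++i)
                mcol[mi++] = (typename MT::elem_type)row[i];
            }
          }
          ++col;
        }
}

// Scatter-add DX (n_slab x K) back onto the input-shaped gradient buffer
// (accumulated in the gemm element type; cast to double once at the end).
template <typename MT>
static void col2im_slab(typename MT::elem_type* dx, const IntegerVector& xd,
                        const IntegerVector& kd, const int* od,
                        int z0, int zn, const MT& DX) {
  typedef typename MT::elem_type eT;
  const int ox = od[0], oy = od[1];
  const int X = xd[0], Y = xd[1];
  const long XY = (long)X * Y, XYZ = XY * xd[2];
  long col = 0;
  for (int c = 0; c < xd[3]; ++c)
    for (int kk = 0; kk < kd[2]; ++kk)
      for (int jj = 0; jj < kd[1]; ++jj)
        for (int ii = 0; ii < kd[0]; ++ii) {
          const eT* mcol = DX.colptr(col);
          long mi = 0;
          for (int z = z0; z < z0 + zn; ++z) {
            eT* base = dx + c * XYZ + (long)(z + kk) * XY;
            for (int j = 0; j < oy; ++j) {
              eT* row = base + (long)(j + jj) * X + ii;
              for (int i = 0; i < ox; ++i) row[i] += mcol[mi++];
            }
          }
          ++col;
        }
}

static int slab_depth(long oxy, long K, size_t elem, int oz) {
  int zn = (int)(SLAB_BYTES / ((double)oxy * K * elem));
  if (zn < 1) zn = 1;
  if (zn > oz) zn = oz;
  return zn;
}

// slope < 0: plain convolution output. slope >= 0: fused leaky ReLU — the
// returned list holds the activation and the pre-activation sign mask.
// keep_ws: additionally return an external pointer to the im2col slabs.
template <typename eT>
static SEXP conv3d_fwd_t(const NumericVector& x, const NumericVector& W,
                         const NumericVector& b, double slope = -1.0,
                         bool keep_ws = false) {
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  IntegerVector kd = IntegerVector::create(wd[0], wd[1], wd[2]);
  const int Cin = wd[3], Cout = wd[4];
  if (xd[3] != Cin) stop("conv3d: input channels (%d) != kernel channels (%d)", xd[3], Cin);
  int od[3];
  for (int a = 0; a < 3; ++a) {
    od[a] = xd[a] - kd[a] + 1;
    if (od[a] < 1) stop("conv3d: input extent %d too small for kernel %d on axis %d",
                        xd[a], kd[a], a + 1);
  }
  const long K = (long)kd[0] * kd[1] * kd[2] * Cin;
  const long oxy = (long)od[0] * od[1];
  const long oxyz = oxy * od[2];

  arma::Mat<eT> Wm(K, Cout);
  for (long i = 0; i < K * Cout; ++i) Wm.memptr()[i] = (eT)W[i];
  arma::Row<eT> brow(Cout);
  for (int c = 0; c < Cout; ++c) brow[c] = (eT)b[c];

  NumericVector out((R_xlen_t)(oxyz * Cout));
  IntegerVector odim = IntegerVector::create(od[0], od[1], od[2], Cout);
  out.attr("dim") = odim;
  LogicalVector pos;
  if (slope >= 0) {
    pos = LogicalVector((R_xlen_t)(oxyz * Cout));
    pos.attr("dim") = odim;
  }
  const int zn0 = slab_depth(oxy, K, sizeof(eT), od[2]);
  Rcpp::XPtr<ConvWS<eT> > ws(new ConvWS<eT>(), true);
  arma::Mat<eT> Mlocal;
  for (int z0 = 0; z0 < od[2]; z0 += zn0) {
    const int zn = std::min(zn0, od[2] - z0);
    if (keep_ws) ws->slabs.push_back(arma::Mat<eT>());
    arma::Mat<eT>& M = keep_ws ? ws->slabs.back() : Mlocal;
    M.set_size(oxy * zn, K);
    im2col_slab(x.begin(), xd, kd, od, z0, zn, M);
    arma::Mat<eT> O = M * Wm;
    O.each_row() += brow;
    for (int c = 0; c < Cout; ++c) {
      double* dst = REAL(out) + c * oxyz + z0 * oxy;
      const eT* src = O.colptr(c);
      if (slope < 0) {
        for (long i = 0; i < oxy * zn; ++i) dst[i] = (double)src[i];
      } else {
        int* pp = LOGICAL(pos) + c * oxyz + z0 * oxy;
        for (long i = 0; i < oxy * zn; ++i) {
          const double v = (double)src[i];
          const bool p = v > 0;
          dst[i] = p ? v : slope * v;
          pp[i] = p;
        }
      }
    }
  }
  if (slope < 0 && !keep_ws) return out;
  List res = (slope < 0) ? List::create(Named("a") = out)
                         : List::create(Named("a") = out, Named("pos") = pos);
  if (keep_ws) res["ws"] = ws;
  return res;
}

template <typename eT>
static List conv3d_bwd_t(const NumericVector& x, const NumericVector& W,
                         const NumericVector& dout, bool need_dx, SEXP wsx) {
  ConvWS<eT>* ws = NULL;
  if (wsx != R_NilValue) ws = Rcpp::XPtr<ConvWS<eT> >(wsx).get();
  IntegerVector xd = x.attr("dim"), wd = W.attr("dim");
  IntegerVector kd = IntegerVector::create(wd[0], wd[1], wd[2]);
  const int Cin = wd[3], Cout = wd[4];
  int od[3];
  for (int a = 0; a < 3; ++a) od[a] = xd[a] - kd[a] + 1;
  IntegerVector dd = dout.attr("dim");
  for (int a = 0; a < 3; ++a)
    if (dd[a] != od[a]) stop("conv3d backward: dout shape mismatch on axis %d", a + 1);
  if (dd[3] != Cout) stop("conv3d backward: dout channels mismatch");
  const long K = (long)kd[0] * kd[1] * kd[2] * Cin;
  const long oxy = (long)od[0] * od[1];
  const long oxyz = oxy * od[2];

  arma::Mat<eT> Wm(K, Cout);
  for (long i = 0; i < K * Cout; ++i) Wm.memptr()[i] = (eT)W[i];
  // materialized transpose: gemm with a lazily-transposed skinny B is slow
  const arma::Mat<eT> WmT = Wm.t();

  arma::mat dWacc(K, Cout, arma::fill::zeros);
  NumericVector db(Cout);
  NumericVector dx;
  const long nx = (long)xd[0] * xd[1] * xd[2] * xd[3];
  std::vector<eT> dxbuf;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)nx);
    dx.attr("dim") = IntegerVector::create(xd[0], xd[1], xd[2], xd[3]);
    dxbuf.assign(nx, (eT)0);
  }

  const int zn0 = slab_depth(oxy, K, sizeof(eT), od[2]);
  arma::Mat<eT> Mlocal, Dm;
  int slab_i = 0;
  for (int z0 = 0; z0 < od[2]; z0 += zn0, ++slab_i) {
    const int zn = std::min(zn0, od[2] - z0);
    Dm.set_size(oxy * zn, Cout);
    for (int c = 0; c < Cout; ++c) {
      const double* src = REAL(dout) + c * oxyz + z0 * oxy;
      eT* dst = Dm.colptr(c);
      for (long i = 0; i < oxy * zn; ++i) dst[i] = (eT)src[i];
    }
    const bool have_ws = ws && slab_i < (int)ws->slabs.size() &&
      ws->slabs[slab_i].n_rows == (arma::uword)(oxy * zn);
    if (!have_ws) {
      Mlocal.set_size(oxy * zn, K);
      im2col_slab(x.begin(), xd, kd, od, z0, zn, Mlocal);
    }
    const arma::Mat<eT>& M = have_ws ? ws->slabs[slab_i] : Mlocal;
    dWacc += arma::conv_to<arma::mat>::from(M.t() * Dm);
    if (need_dx) {
      arma::Mat<eT> DX = Dm * WmT;
      col2im_slab<arma::Mat<eT> >(dxbuf.data(), xd, kd, od, z0, zn, DX);
    }
  }
  if (need_dx) {
    double* dp = REAL(dx);
    for (long i = 0; i < nx; ++i) dp[i] = (double)dxbuf[i];
  }
  for (int c = 0; c < Cout; ++c) {
    double s = 0;
    const double* src = REAL(dout) + c * oxyz;
    for (long i = 0; i < oxyz; ++i) s += src[i];
    db[c] = s;
  }
  NumericVector dW(wrap(dWacc));
  dW.attr("dim") = wd;
  List res = List::create(Named("dW") = dW, Named("db") = db);
  if (need_dx) res["dx"] = dx;
  return res;
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
SEXP conv3d_fwd_cpp(NumericVector x, NumericVector W, NumericVector b,
                    bool single = true, double slope = -1.0,
                    bool keep_ws = false) {
  return single ? conv3d_fwd_t<float>(x, W, b, slope, keep_ws)
                : conv3d_fwd_t<double>(x, W, b, slope, keep_ws);
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd_cpp(NumericVector x, NumericVector W, NumericVector dout,
                    bool need_dx = true, bool single = true,
                    SEXP ws = R_NilValue) {
  return single ? conv3d_bwd_t<float>(x, W, dout, need_dx, ws)
                : conv3d_bwd_t<double>(x, W, dout, need_dx, ws);
}
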