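// Elementwise and pooling primitives for the network hot path.
// Semantics mirror the reference R implementations retained in the test
// suite's oracles: leaky ReLU, and per-axis-factor max pooling where ties
// go to the first candidate in (x, y, z) offset order.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".lrelu_fwd")]]
List lrelu_fwd_cpp(NumericVector z, double slope) {
  R_xlen_t n = z.size();
  NumericVector a(n);
  LogicalVector pos(n);
  const double* zp = z.begin();
  double* ap = a.begin();
  int* pp = pos.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = zp[i];
    const bool p = v > 0;
    ap[i] = p ? v : slope * v;
    pp[i] = p;
  }
  a.attr("dim") = z.attr("dim");
  pos.attr("dim") = z.attr("dim");
  return List::create(Named("a") = a, Named("pos") = pos);
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd_cpp(NumericVector dout, LogicalVector pos, double slope) {
  R_xlen_t n = dout.size();
  NumericVector dx(n);
  const double* dp = dout.begin();
  const int* pp = pos.begin();
  double* xp = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = pp[i] ? dp[i] : slope * dp[i];
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd_cpp(NumericVector x, IntegerVector f) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int ox = X / f[0], oy = Y / f[1], oz = Z / f[2];
  const long oxyz = (long)ox * oy * oz;
  NumericVector out(oxyz * C);
  IntegerVector arg(oxyz * C);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  arg.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ap = arg.begin();
  const long XY = (long)X * Y, XYZ = XY * Z;
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        long oi = c * oxyz + (long)k * ox * oy + (long)j * ox;
        for (int i = 0; i < ox; ++i) {
          double best = -1e300;
          int barg = 0, cid = 0;
          for (int dz = 0; dz < f[2]; ++dz)
            for (int dy = 0; dy < f[1]; ++dy)
              for (int dx = 0; dx < f[0]; ++dx) {
                ++cid;
                const double v = xp[c * XYZ + (long)(k * f[2] + dz) * XY +
                                    (long)(j * f[1] + dy) * X + i * f[0] + dx];
                if (v > best) { best = v; barg = cid; }
              }
          op[oi + i] = best;
          ap[oi + i] = barg;
        }
      }
  return List::create(Named("out") = out, Named("arg") = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector arg,
                              IntegerVector f, IntegerVector in_dim) {
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2], C = in_dim[3];
  IntegerVector od = dout.attr("dim");
  const int ox = od[0], oy = od[1], oz = od[2];
  const long oxyz = (long)ox * oy * oz;
  NumericVector dx((long)X * Y * Z * C);
  dx.attr("dim") = in_dim;
  const double* dp = dout.begin();
  const int* ap = arg.begin();
  double* xp = dx.begin();
  const long XY = (long)X * Y, XYZ = XY * Z;
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j) {
        long oi = c * oxyz + (long)k * ox * oy + (long)j * ox;
        for (int i = 0; i < ox; ++i) {
          const int cid = ap[oi + i] - 1;
          const int dz = cid / (f[0] * f[1]);
          const int dy = (cid / f[0]) % f[1];
          const int dxo = cid % f[0];
          xp[c * XYZ + (long)(k * f[2] + dz) * XY +
             (long)(j * f[1] + dy) * X + i * f[0] + dxo] = dp[oi + i];
        }
      }
  return dx;
}
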