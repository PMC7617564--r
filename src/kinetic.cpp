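#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Tissue compartment prediction (M0 = 1) at readout times t for label-to-
// crusher times lct. Mirrors the R reference implementation vs_model();
// the two routes are cross-checked in the test suite.
static inline void tissue_pred(double f, double bd,
                               const NumericVector& lct,
                               const NumericVector& t,
                               double alpha, double alpha_bgs,
                               double t1b, double t1t, double lambda,
                               std::vector<double>& out) {
  const int n = lct.size();
  const double amp = 2.0 * alpha * alpha_bgs;
  if (f == 0.0) { std::fill(out.begin(), out.end(), 0.0); return; }
  // e^{-t/T1_blood} e^{k t} = e^{-t/T1'} with 1/T1' = 1/T1_tissue + f/lambda
  const double inv_t1p = 1.0 / t1t + f / lambda;
  const double k = 1.0 / t1b - inv_t1p;
  for (int i = 0; i < n; ++i) {
    double tau = bd < lct[i] ? bd : lct[i];
    if (tau <= 0.0) { out[i] = 0.0; continue; }
    double x = k * tau;
    double frac = std::abs(x) < 1e-6 ? 1.0 - x / 2.0 + x * x / 6.0
                                     : -std::expm1(-x) / x;
    out[i] = amp * f * tau * std::exp(-t[i] * inv_t1p) * frac;
  }
}

// Sum of squares profiled over (macro_bv, tau_macro): the macro term is
// linear in macro_bv and piecewise constant in tau_macro with breakpoints
// at the readout times, so the best macro fit for a given tissue residual
// is found in one cumulative-sum pass.
// [[Rcpp::export]]
double cpp_profile_obj(NumericVector fb, NumericVector lct, NumericVector t,
                       NumericVector dmn, NumericVector bsig,
                       NumericVector cum_bb,
                       double alpha, double alpha_bgs,
                       double t1b, double t1t, double lambda) {
  const int n = lct.size();
  std::vector<double> tis(n);
  tissue_pred(fb[0], fb[1], lct, t, alpha, alpha_bgs, t1b, t1t, lambda, tis);
  double ss0 = 0.0, cbr = 0.0, best;
  std::vector<double> r0(n);
  for (int i = 0; i < n; ++i) {
    r0[i] = dmn[i] - tis[i];
    ss0 += r0[i] * r0[i];
  }
  best = ss0;
  for (int j = 0; j < n; ++j) {
    cbr += bsig[j] * r0[j];
    double sse = ss0 - cbr * cbr / cum_bb[j];
    if (sse < best) best = sse;
  }
  return best;
}

static double profile_obj(double f, double bd,
                          const NumericVector& lct, const NumericVector& t,
                          const NumericVector& dmn, const NumericVector& bsig,
                          const NumericVector& cum_bb,
                          double alpha, double alpha_bgs,
                          double t1b, double t1t, double lambda,
                          std::vector<double>& tis) {
  const int n = lct.size();
  tissue_pred(f, bd, lct, t, alpha, alpha_bgs, t1b, t1t, lambda, tis);
  double ss0 = 0.0, cbr = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = dmn[i] - tis[i];
    tis[i] = r;                       // reuse buffer for residual
    ss0 += r * r;
  }
  double best = ss0;
  for (int j = 0; j < n; ++j) {
    cbr += bsig[j] * tis[j];
    double sse = ss0 - cbr * cbr / cum_bb[j];
    if (sse < best) best = sse;
  }
  return R_FINITE(best) ? best : DBL_MAX;
}

// Generic 2-D Nelder-Mead used by the exploration routine below.
// Writes the best point into out[0..1] and returns its objective value.
template <typename F>
static double nm2_min(F f, const double* start, const double* scale,
                      double tol, int maxeval, double* out) {
  int nev = 0;
  auto g = [&](const double* p) { ++nev; return f(p); };
  // simplex of 3 vertices in 2-D
  double v[3][2], fv[3];
  for (int i = 0; i < 3; ++i) { v[i][0] = start[0]; v[i][1] = start[1]; }
  v[1][0] += scale[0];
  v[2][1] += scale[1];
  for (int i = 0; i < 3; ++i) fv[i] = g(v[i]);
  while (nev < maxeval) {
    // order vertices: lo, mid, hi
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    int mid = 3 - lo - hi;
    if (lo == hi) mid = (lo + 1) % 3;
    if (fv[hi] - fv[lo] <= tol * (std::abs(fv[lo]) + tol)) break;
    double c0 = 0.5 * (v[lo][0] + v[mid][0]);   // centroid excluding worst
    double c1 = 0.5 * (v[lo][1] + v[mid][1]);
    double xr[2] = { c0 + (c0 - v[hi][0]), c1 + (c1 - v[hi][1]) };
    double fr = g(xr);
    if (fr < fv[lo]) {
      double xe[2] = { c0 + 2.0 * (c0 - v[hi][0]), c1 + 2.0 * (c1 - v[hi][1]) };
      double fe = g(xe);
      if (fe < fr) { v[hi][0] = xe[0]; v[hi][1] = xe[1]; fv[hi] = fe; }
      else { v[hi][0] = xr[0]; v[hi][1] = xr[1]; fv[hi] = fr; }
    } else if (fr < fv[mid]) {
      v[hi][0] = xr[0]; v[hi][1] = xr[1]; fv[hi] = fr;
    } else {
      double xc[2] = { c0 + 0.5 * (v[hi][0] - c0), c1 + 0.5 * (v[hi][1] - c1) };
      double fc = g(xc);
      if (fc < fv[hi]) { v[hi][0] = xc[0]; v[hi][1] = xc[1]; fv[hi] = fc; }
      else {                                   // shrink towards best
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          v[i][0] = v[lo][0] + 0.5 * (v[i][0] - v[lo][0]);
          v[i][1] = v[lo][1] + 0.5 * (v[i][1] - v[lo][1]);
          fv[i] = g(v[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (fv[i] < fv[lo]) lo = i;
  out[0] = v[lo][0];
  out[1] = v[lo][1];
  return fv[lo];
}

// Multi-start exploration, exhaustive over macro inclusion sets.
//
// For a fixed inclusion set J = {readout times t[0..j-1]} the macro
// amplitude enters linearly and is profiled in closed form, leaving a
// smooth 2-parameter (f, bd) least-squares problem solved by Nelder-Mead
// from every (f, bd) start. Returns one row per (set, start):
// columns f, bd, j (inclusion count), value.
// [[Rcpp::export]]
NumericMatrix cpp_explore(NumericVector lct, NumericVector t,
                          NumericVector dmn, NumericVector bsig,
                          NumericVector f_starts, NumericVector bd_starts,
                          double alpha, double alpha_bgs,
                          double t1b, double t1t, double lambda,
                          double tol, int maxeval) {
  const int n = lct.size();
  const int nf = f_starts.size(), nb = bd_starts.size();
  std::vector<double> tis(n);
  NumericMatrix res((n + 1) * nf * nb, 4);
  int row = 0;
  for (int j = 0; j <= n; ++j) {
    double bb = 0.0;
    for (int i = 0; i < j; ++i) bb += bsig[i] * bsig[i];
    auto obj = [&](const double* p) {
      tissue_pred(p[0], p[1], lct, t, alpha, alpha_bgs, t1b, t1t, lambda,
                  tis);
      double ss = 0.0, br = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = dmn[i] - tis[i];
        ss += r * r;
        if (i < j) br += bsig[i] * r;
      }
      double v = j > 0 ? ss - br * br / bb : ss;
      return R_FINITE(v) ? v : DBL_MAX;
    };
    for (int a = 0; a < nf; ++a)
      for (int b = 0; b < nb; ++b) {
        double start[2] = { f_starts[a], bd_starts[b] };
        double scale[2] = { 0.005, 0.4 };
        double out[2];
        double val = nm2_min(obj, start, scale, tol, maxeval, out);
        res(row, 0) = out[0];
        res(row, 1) = out[1];
        res(row, 2) = (double)j;
        res(row, 3) = val;
        ++row;
      }
  }
  return res;
}

// Full four-parameter normalised sum of squares (par = f, bd, mbv, tmacro).
// [[Rcpp::export]]
double cpp_nobj(NumericVector par, NumericVector lct, NumericVector t,
                NumericVector dmn,
                double alpha, double alpha_bgs,
                double t1b, double t1t, double lambda) {
  const int n = lct.size();
  std::vector<double> tis(n);
  tissue_pred(par[0], par[1], lct, t, alpha, alpha_bgs, t1b, t1t, lambda, tis);
  const double amp = 2.0 * alpha * alpha_bgs;
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double mac = t[i] <= par[3] ? amp * par[2] * std::exp(-t[i] / t1b) : 0.0;
    double r = dmn[i] - tis[i] - mac;
    sse += r * r;
  }
  return sse;
}
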