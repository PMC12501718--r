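#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Mono-exponential inversion-recovery fitting engine.
//
// Model (signed): s(TI) = a + b * exp(-TI / T1).
// Magnitude data lose the sign of the pre-null samples; the polarity is
// restored by re-negating the leading samples up to a candidate boundary
// near the minimum-magnitude point and keeping the lowest-SSE fit.
// Minimisation is a direct Nelder-Mead simplex search over (a, b, T1).

static double ir_sse(const double* p, const double* ti, const double* z,
                     const double* w, int n) {
  const double a = p[0], b = p[1], t1 = p[2];
  if (t1 <= 0.0 || !std::isfinite(t1)) return 1e300;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double r = z[i] - (a + b * std::exp(-ti[i] / t1));
    s += w[i] * r * r;
  }
  return s;
}

struct NMFit {
  double par[3];
  double value;
  bool converged;
};

// Standard Nelder-Mead (reflection 1, expansion 2, contraction 0.5,
// shrink 0.5) on the 3-parameter IR SSE. ftol is an absolute tolerance on
// the simplex function spread; xtol a relative tolerance on parameters.
static NMFit nelder_mead(const double* x0, const double* ti, const double* z,
                         const double* w, int n, double ftol, double xtol,
                         int maxit) {
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  double sx[4][3];
  double fv[4];
  for (int i = 0; i < 3; ++i) sx[0][i] = x0[i];
  for (int j = 1; j < 4; ++j) {
    for (int i = 0; i < 3; ++i) sx[j][i] = x0[i];
    const double step = (x0[j - 1] != 0.0) ? 0.1 * std::fabs(x0[j - 1]) : 0.1;
    sx[j][j - 1] += step;
  }
  for (int j = 0; j < 4; ++j) fv[j] = ir_sse(sx[j], ti, z, w, n);

  int ord[4] = {0, 1, 2, 3};
  bool converged = false;
  int it = 0;
  for (; it < maxit; ++it) {
    // order vertices by function value
    std::sort(ord, ord + 4, [&](int i, int j) { return fv[i] < fv[j]; });
    const int lo = ord[0], hi = ord[3], nh = ord[2];

    // convergence: function spread and parameter spread
    double pspread = 0.0;
    for (int i = 0; i < 3; ++i) {
      double mn = sx[0][i], mx = sx[0][i];
      for (int j = 1; j < 4; ++j) {
        mn = std::min(mn, sx[j][i]);
        mx = std::max(mx, sx[j][i]);
      }
      const double rel = (mx - mn) / (std::fabs(sx[lo][i]) + xtol);
      pspread = std::max(pspread, rel);
    }
    if (std::fabs(fv[hi] - fv[lo]) <= ftol && pspread <= xtol) {
      converged = true;
      break;
    }

    double cen[3];  // centroid of all but worst
    for (int i = 0; i < 3; ++i) {
      cen[i] = 0.0;
      for (int j = 0; j < 4; ++j)
        if (j != hi) cen[i] += sx[j][i];
      cen[i] /= 3.0;
    }
    double xr[3];
    for (int i = 0; i < 3; ++i) xr[i] = cen[i] + alpha * (cen[i] - sx[hi][i]);
    const double fr = ir_sse(xr, ti, z, w, n);

    if (fr < fv[lo]) {
      double xe[3];
      for (int i = 0; i < 3; ++i) xe[i] = cen[i] + gamma * (xr[i] - cen[i]);
      const double fe = ir_sse(xe, ti, z, w, n);
      if (fe < fr) {
        for (int i = 0; i < 3; ++i) sx[hi][i] = xe[i];
        fv[hi] = fe;
      } else {
        for (int i = 0; i < 3; ++i) sx[hi][i] = xr[i];
        fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      for (int i = 0; i < 3; ++i) sx[hi][i] = xr[i];
      fv[hi] = fr;
    } else {
      // contraction (outside if fr < f(hi), inside otherwise)
      double xc[3];
      if (fr < fv[hi]) {
        for (int i = 0; i < 3; ++i) xc[i] = cen[i] + rho * (xr[i] - cen[i]);
      } else {
        for (int i = 0; i < 3; ++i) xc[i] = cen[i] - rho * (cen[i] - sx[hi][i]);
      }
      const double fc = ir_sse(xc, ti, z, w, n);
      if (fc < std::min(fr, fv[hi])) {
        for (int i = 0; i < 3; ++i) sx[hi][i] = xc[i];
        fv[hi] = fc;
      } else {
        // shrink toward best
        for (int j = 0; j < 4; ++j) {
          if (j == lo) continue;
          for (int i = 0; i < 3; ++i)
            sx[j][i] = sx[lo][i] + sigma * (sx[j][i] - sx[lo][i]);
          fv[j] = ir_sse(sx[j], ti, z, w, n);
        }
      }
    }
  }
  std::sort(ord, ord + 4, [&](int i, int j) { return fv[i] < fv[j]; });
  NMFit out;
  for (int i = 0; i < 3; ++i) out.par[i] = sx[ord[0]][i];
  out.value = fv[ord[0]];
  out.converged = converged;
  return out;
}

// Fit one candidate sign assignment z (signed data); initial T1 t10 with
// two restarts at t10 * {0.5, 2} on non-convergence.
static NMFit fit_candidate(const std::vector<double>& z, const double* ti,
                           const double* w, int n, double t10, double a0,
                           double ftol, double xtol, int maxit) {
  const double b0 = -(a0 + std::fabs(z[0]));
  const double scales[3] = {1.0, 0.5, 2.0};
  NMFit best;
  best.value = R_PosInf;
  best.converged = false;
  for (int k = 0; k < 3; ++k) {
    double x0[3] = {a0, b0, t10 * scales[k]};
    NMFit f = nelder_mead(x0, ti, z.data(), w, n, ftol, xtol, maxit);
    if (k == 0 || f.value < best.value) best = f;
    if (f.converged) break;
  }
  // restart the simplex once at the optimum: a fresh simplex escapes the
  // degenerate final shape and typically gains 1-2 digits
  NMFit p = nelder_mead(best.par, ti, z.data(), w, n, ftol, xtol, maxit);
  if (p.value <= best.value) {
    p.converged = p.converged || best.converged;
    best = p;
  }
  return best;
}

// Fit one magnitude series.
// mode 0 = polarity-restored (all-TI): candidate boundaries near the
//          minimum-magnitude index (or every boundary when all_boundaries).
// mode 1 = no restoration (long-TI): samples taken as positive.
// Returns {a, b, t1, sse, nflip, converged, ok}.
static void fit_series(const double* y, const double* ti, const double* w,
                       int n, int mode, bool all_boundaries, double* out) {
  double ymax = 0.0;
  bool allzero = true;
  for (int i = 0; i < n; ++i) {
    if (y[i] != 0.0) allzero = false;
    ymax = std::max(ymax, std::fabs(y[i]));
  }
  if (allzero) {
    out[0] = out[1] = out[2] = out[3] = NA_REAL;
    out[4] = NA_REAL;
    out[5] = 0;
    out[6] = 0;
    return;
  }

  int imin = 0;
  for (int i = 1; i < n; ++i)
    if (y[i] < y[imin]) imin = i;

  std::vector<int> cand;  // boundary j: indices <= j are negated; -1 = none
  if (mode == 1) {
    cand.push_back(-1);
  } else if (all_boundaries) {
    for (int j = -1; j < n; ++j) cand.push_back(j);
  } else {
    int js[4] = {-1, imin - 1, imin, imin + 1};
    for (int k = 0; k < 4; ++k) {
      int j = js[k];
      if (j < -1) j = -1;
      if (j > n - 1) j = n - 1;
      bool dup = false;
      for (size_t q = 0; q < cand.size(); ++q)
        if (cand[q] == j) dup = true;
      if (!dup) cand.push_back(j);
    }
  }

  const double ftol = 1e-8 * ymax * ymax;
  const double xtol = 1e-6;
  const int maxit = 2000;
  const double a0 = ymax;
  const double t10 = ti[imin] / std::log(2.0);

  NMFit best;
  best.value = R_PosInf;
  best.converged = false;
  int bestj = -1;
  std::vector<double> z(n);
  for (size_t q = 0; q < cand.size(); ++q) {
    const int j = cand[q];
    for (int i = 0; i < n; ++i) z[i] = (i <= j) ? -y[i] : y[i];
    NMFit f = fit_candidate(z, ti, w, n, t10, a0, ftol, xtol, maxit);
    if (f.value < best.value) {
      best = f;
      bestj = j;
    }
  }
  out[0] = best.par[0];
  out[1] = best.par[1];
  out[2] = best.par[2];
  out[3] = best.value;
  out[4] = bestj + 1;  // number of leading samples negated
  out[5] = best.converged ? 1 : 0;
  out[6] = (best.converged && std::isfinite(best.value)) ? 1 : 0;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_fit_map")]]
List cpp_fit_map(NumericMatrix Y, NumericVector ti, int mode,
                 bool all_boundaries, NumericMatrix weights) {
  const int nvox = Y.nrow();
  const int n = Y.ncol();
  if (ti.size() != n) stop("length(ti) must equal ncol(Y)");
  const bool have_w = weights.nrow() == nvox && weights.ncol() == n;
  if (!have_w && weights.nrow() != 0)
    stop("weights must be empty or match dim(Y)");
  std::vector<double> w(n, 1.0);

  NumericVector a(nvox), b(nvox), t1(nvox), sse(nvox);
  IntegerVector nflip(nvox);
  LogicalVector conv(nvox), ok(nvox);
  std::vector<double> yrow(n);
  double out[7];
  for (int v = 0; v < nvox; ++v) {
    bool anyna = false;
    for (int i = 0; i < n; ++i) {
      yrow[i] = Y(v, i);
      if (have_w) w[i] = weights(v, i);
      if (!std::isfinite(yrow[i])) anyna = true;
    }
    if (anyna) {
      a[v] = b[v] = t1[v] = sse[v] = NA_REAL;
      nflip[v] = NA_INTEGER;
      conv[v] = false;
      ok[v] = false;
      continue;
    }
    fit_series(yrow.data(), &ti[0], w.data(), n, mode, all_boundaries, out);
    a[v] = out[0];
    b[v] = out[1];
    t1[v] = out[2];
    sse[v] = out[3];
    nflip[v] = ISNA(out[4]) ? NA_INTEGER : (int)out[4];
    conv[v] = out[5] != 0;
    ok[v] = out[6] != 0;
  }
  return List::create(_["a"] = a, _["b"] = b, _["t1"] = t1, _["sse"] = sse,
                      _["nflip"] = nflip, _["converged"] = conv,
                      _["ok"] = ok);
}
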