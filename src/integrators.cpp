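#include <Rcpp.h>
using namespace Rcpp;

// Classical fixed-step fourth-order Runge-Kutta drivers for the oscillator
// models.  Trajectories are stored every `thin` steps (row 0 is the initial
// state).  On divergence (non-finite state, or x3 <= 0 under the power-law
// transcription function) integration stops and the failing time is reported.

struct GoodwinPars {
  double k1, k2, k3, p1, p2, r, n, K;
  int form;      // 0 = power_law f = r/x3^n, 1 = hill f = r/(1+(x3/K)^n)
  double I, Omega;
};

static inline void goodwin_deriv(const double *y, double t,
                                 const GoodwinPars &p, double *dy) {
  double f;
  if (p.form == 0) {
    f = p.r * std::pow(y[2], -p.n);
  } else {
    f = p.r / (1.0 + std::pow(y[2] / p.K, p.n));
  }
  dy[0] = f - p.k1 * y[0];
  if (p.I != 0.0) dy[0] += p.I * std::cos(p.Omega * t);
  dy[1] = p.p1 * y[0] - p.k2 * y[1];
  dy[2] = p.p2 * y[1] - p.k3 * y[2];
}

// [[Rcpp::export]]
List rk4_goodwin_cpp(NumericVector y0, double k1, double k2, double k3,
                     double p1, double p2, double r, double n, int form,
                     double K, double I, double Omega, double dt,
                     int nsteps, int thin) {
  GoodwinPars p{k1, k2, k3, p1, p2, r, n, K, form, I, Omega};
  int nout = nsteps / thin + 1;
  NumericMatrix out(nout, 3);
  double y[3] = {y0[0], y0[1], y0[2]};
  out(0, 0) = y[0]; out(0, 1) = y[1]; out(0, 2) = y[2];
  double a[3], b[3], c[3], d[3], tmp[3];
  int row = 1;
  for (int i = 0; i < nsteps; ++i) {
    double t = i * dt;
    goodwin_deriv(y, t, p, a);
    for (int j = 0; j < 3; ++j) tmp[j] = y[j] + 0.5 * dt * a[j];
    goodwin_deriv(tmp, t + 0.5 * dt, p, b);
    for (int j = 0; j < 3; ++j) tmp[j] = y[j] + 0.5 * dt * b[j];
    goodwin_deriv(tmp, t + 0.5 * dt, p, c);
    for (int j = 0; j < 3; ++j) tmp[j] = y[j] + dt * c[j];
    goodwin_deriv(tmp, t + dt, p, d);
    for (int j = 0; j < 3; ++j)
      y[j] += dt / 6.0 * (a[j] + 2.0 * b[j] + 2.0 * c[j] + d[j]);
    bool bad = !(R_finite(y[0]) && R_finite(y[1]) && R_finite(y[2]));
    if (!bad && form == 0 && y[2] <= 0.0) bad = true;
    if (bad) {
      return List::create(_["values"] = out, _["rows"] = row,
                          _["diverged"] = true, _["t_fail"] = (i + 1) * dt);
    }
    if ((i + 1) % thin == 0 && row < nout) {
      out(row, 0) = y[0]; out(row, 1) = y[1]; out(row, 2) = y[2];
      ++row;
    }
  }
  return List::create(_["values"] = out, _["rows"] = row,
                      _["diverged"] = false, _["t_fail"] = NA_REAL);
}

static inline void lv_deriv(const double *y, double a, double b,
                            double e, double ep, double *dy) {
  dy[0] = a * y[0] - e * y[0] * y[1];
  dy[1] = -b * y[1] + ep * y[0] * y[1];
}

// [[Rcpp::export]]
List rk4_lv_cpp(NumericVector y0, double a, double b, double e, double ep,
                double dt, int nsteps, int thin) {
  int nout = nsteps / thin + 1;
  NumericMatrix out(nout, 2);
  double y[2] = {y0[0], y0[1]};
  out(0, 0) = y[0]; out(0, 1) = y[1];
  double s1[2], s2[2], s3[2], s4[2], tmp[2];
  int row = 1;
  for (int i = 0; i < nsteps; ++i) {
    lv_deriv(y, a, b, e, ep, s1);
    for (int j = 0; j < 2; ++j) tmp[j] = y[j] + 0.5 * dt * s1[j];
    lv_deriv(tmp, a, b, e, ep, s2);
    for (int j = 0; j < 2; ++j) tmp[j] = y[j] + 0.5 * dt * s2[j];
    lv_deriv(tmp, a, b, e, ep, s3);
    for (int j = 0; j < 2; ++j) tmp[j] = y[j] + dt * s3[j];
    lv_deriv(tmp, a, b, e, ep, s4);
    for (int j = 0; j < 2; ++j)
      y[j] += dt / 6.0 * (s1[j] + 2.0 * s2[j] + 2.0 * s3[j] + s4[j]);
    if (!(R_finite(y[0]) && R_finite(y[1])) || y[0] <= 0.0 || y[1] <= 0.0) {
      return List::create(_["values"] = out, _["rows"] = row,
                          _["diverged"] = true, _["t_fail"] = (i + 1) * dt);
    }
    if ((i + 1) % thin == 0 && row < nout) {
      out(row, 0) = y[0]; out(row, 1) = y[1];
      ++row;
    }
  }
  return List::create(_["values"] = out, _["rows"] = row,
                      _["diverged"] = false, _["t_fail"] = NA_REAL);
}

static inline void vdp_deriv(const double *y, double e, double *dy) {
  dy[0] = y[1];
  dy[1] = e * (1.0 - y[0] * y[0]) * y[1] - y[0];
}

// [[Rcpp::export]]
List rk4_vdp_cpp(NumericVector y0, double e, double dt, int nsteps, int thin) {
  int nout = nsteps / thin + 1;
  NumericMatrix out(nout, 2);
  double y[2] = {y0[0], y0[1]};
  out(0, 0) = y[0]; out(0, 1) = y[1];
  double s1[2], s2[2], s3[2], s4[2], tmp[2];
  int row = 1;
  for (int i = 0; i < nsteps; ++i) {
    vdp_deriv(y, e, s1);
    for (int j = 0; j < 2; ++j) tmp[j] = y[j] + 0.5 * dt * s1[j];
    vdp_deriv(tmp, e, s2);
    for (int j = 0; j < 2; ++j) tmp[j] = y[j] + 0.5 * dt * s2[j];
    vdp_deriv(tmp, e, s3);
    for (int j = 0; j < 2; ++j) tmp[j] = y[j] + dt * s3[j];
    vdp_deriv(tmp, e, s4);
    for (int j = 0; j < 2; ++j)
      y[j] += dt / 6.0 * (s1[j] + 2.0 * s2[j] + 2.0 * s3[j] + s4[j]);
    if (!(R_finite(y[0]) && R_finite(y[1]))) {
      return List::create(_["values"] = out, _["rows"] = row,
                          _["diverged"] = true, _["t_fail"] = (i + 1) * dt);
    }
    if ((i + 1) % thin == 0 && row < nout) {
      out(row, 0) = y[0]; out(row, 1) = y[1];
      ++row;
    }
  }
  return List::create(_["values"] = out, _["rows"] = row,
                      _["diverged"] = false, _["t_fail"] = NA_REAL);
}

// Least-squares fit of c0 + A cos(w t) + B sin(w t) to a uniformly sampled
// series (t = t0 + i dt).  Solves the 3x3 normal equations exactly; returns
// (A, B, c0, sse).  Workhorse of the generalized harmonic analysis.
// [[Rcpp::export]]
NumericVector gha_fit_cpp(NumericVector x, double t0, double dt, double w) {
  int n = x.size();
  double Sc = 0, Ss = 0, Scc = 0, Sss = 0, Scs = 0;
  double Sx = 0, Sxc = 0, Sxs = 0;
  for (int i = 0; i < n; ++i) {
    double t = t0 + i * dt;
    double c = std::cos(w * t), s = std::sin(w * t);
    Sc += c; Ss += s; Scc += c * c; Sss += s * s; Scs += c * s;
    Sx += x[i]; Sxc += x[i] * c; Sxs += x[i] * s;
  }
  // normal equations for (c0, A, B)
  double M[3][3] = {{(double)n, Sc, Ss}, {Sc, Scc, Scs}, {Ss, Scs, Sss}};
  double v[3] = {Sx, Sxc, Sxs};
  // gaussian elimination with partial pivoting (3x3)
  int idx[3] = {0, 1, 2};
  for (int col = 0; col < 3; ++col) {
    int piv = col;
    for (int rr = col + 1; rr < 3; ++rr)
      if (std::fabs(M[idx[rr]][col]) > std::fabs(M[idx[piv]][col])) piv = rr;
    std::swap(idx[col], idx[piv]);
    double diag = M[idx[col]][col];
    if (std::fabs(diag) < 1e-300) diag = 1e-300;
    for (int rr = col + 1; rr < 3; ++rr) {
      double fac = M[idx[rr]][col] / diag;
      for (int cc = col; cc < 3; ++cc) M[idx[rr]][cc] -= fac * M[idx[col]][cc];
      v[idx[rr]] -= fac * v[idx[col]];
    }
  }
  double sol[3];
  for (int col = 2; col >= 0; --col) {
    double acc = v[idx[col]];
    for (int cc = col + 1; cc < 3; ++cc) acc -= M[idx[col]][cc] * sol[cc];
    sol[col] = acc / (std::fabs(M[idx[col]][col]) < 1e-300 ? 1e-300
                                                           : M[idx[col]][col]);
  }
  double c0 = sol[0], A = sol[1], B = sol[2];
  double sse = 0;
  for (int i = 0; i < n; ++i) {
    double t = t0 + i * dt;
    double res = x[i] - c0 - A * std::cos(w * t) - B * std::sin(w * t);
    sse += res * res;
  }
  return NumericVector::create(_["A"] = A, _["B"] = B, _["c0"] = c0,
                               _["sse"] = sse);
}

// Residual sum of squares over a grid of angular frequencies (coarse scan
// used to locate the dominant component before golden-section refinement).
// [[Rcpp::export]]
NumericVector gha_scan_cpp(NumericVector x, double t0, double dt,
                           NumericVector w_grid) {
  int m = w_grid.size();
  NumericVector sse(m);
  for (int g = 0; g < m; ++g) {
    NumericVector fit = gha_fit_cpp(x, t0, dt, w_grid[g]);
    sse[g] = fit[3];
  }
  return sse;
}
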