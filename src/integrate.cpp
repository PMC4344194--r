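#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mass-action right-hand side for networks of 1<->1 and 2<->2 reversible
// reactions. Species indices are 0-based; r2/p2 are -1 for linear
// reactions. Clamped species have their derivative forced to zero.
static inline void rhs(const std::vector<int>& r1, const std::vector<int>& r2,
                       const std::vector<int>& p1, const std::vector<int>& p2,
                       const std::vector<double>& kf,
                       const std::vector<double>& kb,
                       const std::vector<char>& clamped,
                       const std::vector<double>& x, std::vector<double>& dx) {
  std::fill(dx.begin(), dx.end(), 0.0);
  const int m = (int)r1.size();
  for (int j = 0; j < m; ++j) {
    double vp = kf[j] * x[r1[j]];
    if (r2[j] >= 0) vp *= x[r2[j]];
    double vm = kb[j] * x[p1[j]];
    if (p2[j] >= 0) vm *= x[p2[j]];
    const double v = vp - vm;
    dx[r1[j]] -= v;
    if (r2[j] >= 0) dx[r2[j]] -= v;
    dx[p1[j]] += v;
    if (p2[j] >= 0) dx[p2[j]] += v;
  }
  for (size_t i = 0; i < dx.size(); ++i)
    if (clamped[i]) dx[i] = 0.0;
}

// Dormand-Prince 5(4), adaptive step, FSAL. Steps producing negative
// concentrations are rejected with a halved step. After each accepted step
// the stationarity residual mean((dx_i/dt)^2) over unclamped species is
// evaluated at the new state; integration stops when it drops below
// residual_tol or when t reaches t_max.
// [[Rcpp::export(name = ".dp45_mass_action")]]
List dp45_mass_action(IntegerVector r1_, IntegerVector r2_, IntegerVector p1_,
                      IntegerVector p2_, NumericVector kf_, NumericVector kb_,
                      NumericVector x0, IntegerVector clamped_, double t_max,
                      double residual_tol, double rtol, double atol,
                      double h_init, double max_steps) {
  const int n = x0.size();
  const int m = r1_.size();
  std::vector<int> r1(r1_.begin(), r1_.end()), r2(r2_.begin(), r2_.end()),
      p1(p1_.begin(), p1_.end()), p2(p2_.begin(), p2_.end());
  std::vector<double> kf(kf_.begin(), kf_.end()), kb(kb_.begin(), kb_.end());
  std::vector<char> clamped(n, 0);
  int n_free = n;
  for (int i = 0; i < clamped_.size(); ++i) {
    clamped[clamped_[i]] = 1;
    --n_free;
  }

  // Butcher tableau (Dormand & Prince 1980)
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  // embedded 4th-order weights
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  std::vector<double> y(x0.begin(), x0.end()), ytmp(n), ynew(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);

  double t = 0.0, h = h_init;
  double residual = R_PosInf;
  bool converged = false, failed = false;
  double steps = 0, rejects = 0;

  rhs(r1, r2, p1, p2, kf, kb, clamped, y, k1);
  if (n_free == 0) { // everything clamped: the initial state is stationary
    converged = true;
    residual = 0.0;
  }

  while (!converged && t < t_max) {
    if (steps + rejects > max_steps) break;
    if (h > t_max - t) h = t_max - t;

    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(r1, r2, p1, p2, kf, kb, clamped, ytmp, k2);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(r1, r2, p1, p2, kf, kb, clamped, ytmp, k3);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(r1, r2, p1, p2, kf, kb, clamped, ytmp, k4);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(r1, r2, p1, p2, kf, kb, clamped, ytmp, k5);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(r1, r2, p1, p2, kf, kb, clamped, ytmp, k6);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(r1, r2, p1, p2, kf, kb, clamped, ynew, k7);

    bool neg = false, bad = false;
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(ynew[i])) { bad = true; break; }
      if (ynew[i] < 0.0) { neg = true; }
      const double y5 = b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                        b6 * k6[i];
      const double y4 = e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i];
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double e = h * (y5 - y4) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / n);

    if (bad || !std::isfinite(errnorm)) {
      h *= 0.25;
      ++rejects;
      if (h < 1e-14) { failed = true; break; }
      continue;
    }
    if (neg) { // positivity guard: reject and halve
      h *= 0.5;
      ++rejects;
      if (h < 1e-14) { failed = true; break; }
      continue;
    }
    if (errnorm > 1.0) {
      h *= std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      ++rejects;
      if (h < 1e-14) { failed = true; break; }
      continue;
    }

    // accepted; stationarity residual = mean squared concentration change
    // per species and step length
    double res = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!clamped[i]) {
        const double d = (ynew[i] - y[i]) / h;
        res += d * d;
      }
      y[i] = ynew[i];
      k1[i] = k7[i]; // FSAL
    }
    t += h;
    ++steps;
    residual = n_free > 0 ? res / n_free : 0.0;
    if (residual < residual_tol) converged = true;
    double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    h *= std::min(5.0, std::max(0.2, fac));
  }

  return List::create(
      _["x"] = NumericVector(y.begin(), y.end()), _["t_final"] = t,
      _["residual"] = residual, _["converged"] = converged,
      _["failed"] = failed, _["n_accepted"] = steps,
      _["n_rejected"] = rejects);
}
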