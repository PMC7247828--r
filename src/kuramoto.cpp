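// Adaptive Dormand-Prince 5(4) integration of Kuramoto-family phase models.
// The mean-field variants use the O(N) order-parameter identity; the network
// variant uses a dense adjacency matrix-vector product.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::vec;
using arma::mat;

namespace {

// variant: 0 = all-to-all / heterogeneous K (kvec), 1 = firing, 2 = network
struct KuramotoSystem {
  int variant;
  vec omega;
  vec kvec;     // per-oscillator coupling (constant vector for global K)
  vec alpha;    // firing coefficients (variant 1)
  double kglobal;
  const mat *A; // adjacency (variant 2)

  void rhs(const vec &theta, vec &dth) const {
    const arma::uword n = theta.n_elem;
    vec s = arma::sin(theta), c = arma::cos(theta);
    if (variant == 2) {
      // (K/N) * [cos(th_i) (A sin th)_i - sin(th_i) (A cos th)_i]
      vec As = (*A) * s, Ac = (*A) * c;
      dth = omega + (kglobal / double(n)) * (c % As - s % Ac);
    } else {
      double S = arma::accu(s), C = arma::accu(c);
      // K_i/N * sum_j sin(th_j - th_i) = K_i/N * (S cos th_i - C sin th_i)
      dth = omega + (kvec / double(n)) % (S * c - C * s);
      if (variant == 1) dth += alpha % s;
    }
  }
};

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// Integrate from t0 to t1, overwriting y. Returns number of accepted steps.
long dp45_span(const KuramotoSystem &sys, vec &y, double t0, double t1,
               double atol, double rtol, double &h, long max_steps) {
  const arma::uword n = y.n_elem;
  vec k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), ytmp(n), ynew(n),
      err(n);
  double t = t0;
  if (h <= 0) h = 1e-3;
  long accepted = 0, total = 0;
  sys.rhs(y, k1);
  while (t < t1) {
    if (++total > max_steps)
      Rcpp::stop("integrator exceeded %ld steps (t = %g of [%g, %g]); "
                 "the system may be too stiff for the requested tolerances",
                 max_steps, t, t0, t1);
    bool hit_end = false;
    double hs = h;
    if (t + hs >= t1) { hs = t1 - t; hit_end = true; }

    ytmp = y + hs * (a21 * k1);
    sys.rhs(ytmp, k2);
    ytmp = y + hs * (a31 * k1 + a32 * k2);
    sys.rhs(ytmp, k3);
    ytmp = y + hs * (a41 * k1 + a42 * k2 + a43 * k3);
    sys.rhs(ytmp, k4);
    ytmp = y + hs * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
    sys.rhs(ytmp, k5);
    ytmp = y + hs * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    sys.rhs(ytmp, k6);
    ynew = y + hs * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    sys.rhs(ynew, k7); // FSAL
    err = ynew - (y + hs * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 +
                            e7 * k7));
    // scaled RMS error norm (scipy-style)
    double acc = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err[i] / sc;
      acc += r * r;
    }
    double enorm = std::sqrt(acc / double(n));
    if (enorm <= 1.0) {
      t += hs;
      y = ynew;
      k1 = k7;
      ++accepted;
      double fac = (enorm > 0) ? 0.9 * std::pow(enorm, -0.2) : 10.0;
      if (fac > 10.0) fac = 10.0;
      if (!hit_end) h = hs * fac;
      else h = std::max(h, hs * fac);
    } else {
      double fac = 0.9 * std::pow(enorm, -0.2);
      if (fac < 0.2) fac = 0.2;
      h = hs * fac;
      if (hit_end) { /* retry shorter, no longer hitting end */ }
      if (h <= 1e-14 * std::max(1.0, std::fabs(t)))
        Rcpp::stop("step size underflow at t = %g", t);
    }
    Rcpp::checkUserInterrupt();
  }
  return accepted;
}

KuramotoSystem make_system(int variant, const vec &omega, const vec &kvec,
                           const vec &alpha, double kglobal, const mat &A) {
  KuramotoSystem sys;
  sys.variant = variant;
  sys.omega = omega;
  sys.kvec = kvec;
  sys.alpha = alpha;
  sys.kglobal = kglobal;
  sys.A = &A;
  return sys;
}

} // namespace

// [[Rcpp::export(name = ".cpp_kuramoto_integrate")]]
Rcpp::List cpp_kuramoto_integrate(int variant, const arma::vec &theta0,
                                  const arma::vec &omega,
                                  const arma::vec &kvec,
                                  const arma::vec &alpha, double kglobal,
                                  const arma::mat &A, const arma::vec &times,
                                  double atol, double rtol,
                                  double max_steps_per_span) {
  KuramotoSystem sys = make_system(variant, omega, kvec, alpha, kglobal, A);
  const arma::uword nt = times.n_elem, n = theta0.n_elem;
  mat out(nt, n);
  vec y = theta0;
  out.row(0) = y.t();
  double h = 1e-3;
  long steps = 0;
  for (arma::uword k = 1; k < nt; ++k) {
    if (times[k] < times[k - 1]) Rcpp::stop("times must be non-decreasing");
    if (times[k] > times[k - 1])
      steps += dp45_span(sys, y, times[k - 1], times[k], atol, rtol, h,
                         (long)max_steps_per_span);
    out.row(k) = y.t();
  }
  return Rcpp::List::create(Rcpp::Named("phases") = out,
                            Rcpp::Named("steps") = steps);
}

// [[Rcpp::export(name = ".cpp_kuramoto_rhs")]]
arma::vec cpp_kuramoto_rhs(int variant, const arma::vec &theta,
                           const arma::vec &omega, const arma::vec &kvec,
                           const arma::vec &alpha, double kglobal,
                           const arma::mat &A) {
  KuramotoSystem sys = make_system(variant, omega, kvec, alpha, kglobal, A);
  vec dth(theta.n_elem);
  sys.rhs(theta, dth);
  return dth;
}
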