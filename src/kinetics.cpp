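#include <Rcpp.h>
using namespace Rcpp;

// Exact convolution of a piecewise-linear input with exponential kernels.
//
// The tracer input cp is taken to be piecewise linear between the knots
// t[0] < t[1] < ... < t[n-1] (t[0] == 0, zero state before t[0]).  For a
// rate alpha >= 0 the states
//
//   y(t) = int_0^t exp(-alpha (t-u)) cp(u) du
//   z(t) = int_0^t (t-u) exp(-alpha (t-u)) cp(u) du
//
// and their running time-integrals Y, Z are propagated knot-to-knot with
// closed-form segment integrals, so the result is exact for the piecewise
// linear input (no quadrature error).  z/Z are only needed for the confluent
// kernel (alpha1 == alpha2) and are computed when order >= 1.
//
// Per segment of length dt with x = alpha*dt, E = exp(-x) the moments
//   I_k = int_0^dt v^k exp(-alpha v) dv,  k = 0..3
//   G1  = (dt - I0)/alpha          ( = int_0^dt phi1, phi1 = (1-e^{-as})/a )
//   G2  = (dt^2/2 - dt*I0 + I1)/alpha
// are evaluated by stable closed forms, switching to series for small x
// (which also covers alpha == 0 exactly in the polynomial limit).

// [[Rcpp::export(name = ".cppExpConv")]]
List cppExpConv(NumericVector t, NumericVector cp, double alpha, int order) {
  const int n = t.size();
  if (cp.size() != n) stop("t and cp must have equal length");
  if (alpha < 0) stop("alpha must be nonnegative");
  NumericVector y(n), Y(n), z, Z;
  const bool want_z = order >= 1;
  if (want_z) { z = NumericVector(n); Z = NumericVector(n); }

  for (int i = 1; i < n; ++i) {
    const double dt = t[i] - t[i - 1];
    if (!(dt > 0)) stop("t must be strictly increasing");
    const double a = cp[i - 1];          // cp at segment start
    const double c1 = cp[i];             // cp at segment end
    const double b = (c1 - a) / dt;      // slope
    const double x = alpha * dt;
    double E, I0, I1, I2, I3, G1, G2;
    if (x < 1e-3) {
      // series in x (exact at alpha == 0)
      const double x2 = x * x, x3 = x2 * x;
      E  = std::exp(-x);
      I0 = dt * (1.0 - x / 2 + x2 / 6 - x3 / 24);
      I1 = dt * dt * (0.5 - x / 3 + x2 / 8 - x3 / 30);
      I2 = dt * dt * dt * (1.0 / 3 - x / 4 + x2 / 10 - x3 / 36);
      I3 = dt * dt * dt * dt * (0.25 - x / 5 + x2 / 12 - x3 / 42);
      G1 = dt * dt * (0.5 - x / 6 + x2 / 24 - x3 / 120);
      G2 = dt * dt * dt * (1.0 / 6 - x / 24 + x2 / 120 - x3 / 720);
    } else {
      E = std::exp(-x);
      const double em = -std::expm1(-x);  // 1 - E, accurate for small x
      const double a1 = alpha, a2 = a1 * a1, a3 = a2 * a1, a4 = a3 * a1;
      I0 = em / a1;
      I1 = (em - x * E) / a2;
      I2 = (2 * em - x * E * (x + 2)) / a3;
      I3 = (6 * em - x * E * (x * x + 3 * x + 6)) / a4;
      G1 = (dt - I0) / a1;
      G2 = (dt * dt / 2 - dt * I0 + I1) / a1;
    }
    y[i] = E * y[i - 1] + c1 * I0 - b * I1;
    Y[i] = Y[i - 1] + y[i - 1] * I0 + a * G1 + b * G2;
    if (want_z) {
      z[i] = E * (z[i - 1] + dt * y[i - 1]) + c1 * I1 - b * I2;
      Z[i] = Z[i - 1] + z[i - 1] * I0 + y[i - 1] * I1 +
        a * (dt * I1 - I2) + 0.5 * b * (dt * dt * I1 - 2 * dt * I2 + I3);
    }
  }
  if (want_z)
    return List::create(_["y"] = y, _["Y"] = Y, _["z"] = z, _["Z"] = Z);
  return List::create(_["y"] = y, _["Y"] = Y);
}
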